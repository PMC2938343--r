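make_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("expression TSV round trip is exact and small files parse as written", {
  p <- make_tsv(c("gene_id\ta\tb", "g1\t1.0\t2.0", "g2\t3.0\t4.0"))
  x <- read_expression(p)
  expect_identical(dim(x), c(2L, 2L))
  expect_equal(x["g1", "b"], 2)
  expect_equal(x["g2", "a"], 3)

  d <- simulate_dataset(simulation_config(n_genes = 25,
                                          group_sizes = c(3, 3, 3, 3), seed = 5))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression(d$expression, out)
  expect_identical(read_expression(out), d$expression)
})

test_that("malformed expression files fail with located errors", {
  dup <- make_tsv(c("gene_id\ta\ta", "g1\t1\t2"))
  expect_error(read_expression(dup), "duplicated sample column.*a")
  ragged <- make_tsv(c("gene_id\ta\tb", "g1\t1\t2", "g2\t3"))
  expect_error(read_expression(ragged), "line 3")
  bad <- make_tsv(c("gene_id\ta\tb", "g1\t1\t2", "g2\tx\t4"))
  expect_error(read_expression(bad), "line 3.*non-numeric")
})

test_that("phenotype round trip preserves values and validation bites", {
  d <- simulate_dataset(simulation_config(n_genes = 5,
                                          group_sizes = c(2, 2, 2, 2),
                                          n_subtype_genes = 1,
                                          n_survival_genes = 1, seed = 1))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype(d$phenotype, p)
  ph <- read_phenotype(p)
  expect_identical(ph$sample_id, d$phenotype$sample_id)
  expect_equal(ph$time, d$phenotype$time)
  expect_identical(ph$group, d$phenotype$group)

  bad <- make_tsv(c("sample_id\tsubtype\tstatus\ttime\tevent",
                    "s1\tABC\tdead\t1.5\t0",
                    "s2\tGCB\talive\t2.0\t0"))
  expect_error(read_phenotype(bad), "dead.*event")
})

test_that("duplicate probes average to their gene", {
  m <- matrix(c(1, 3, 3, 5), nrow = 2,
              dimnames = list(c("p1", "p2"), c("a", "b")))
  out <- average_duplicate_probes(m, c(p1 = "geneA", p2 = "geneA"))
  expect_identical(rownames(out), "geneA")
  expect_equal(unname(out["geneA", ]), c(2, 4), ignore_attr = TRUE)
})

test_that("probe averaging is identity up to renaming and drops unmapped probes", {
  m <- matrix(1:6, nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  out <- average_duplicate_probes(m, c(p1 = "gA", p2 = "gB", p3 = "gC"))
  expect_identical(unname(out), unname(m) * 1.0)
  expect_identical(rownames(out), c("gA", "gB", "gC"))

  out2 <- average_duplicate_probes(m, c(p1 = "gA", p3 = "gC"))
  expect_identical(rownames(out2), c("gA", "gC"))
  expect_error(average_duplicate_probes(m, character(0)), "empty")
})

test_that("low-intensity filter keeps exactly the genes above threshold", {
  m <- matrix(c(1, 1, 5, 5, 10, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_identical(rownames(filter_low_intensity(m, min_mean = 4)), c("g2", "g3"))
  expect_identical(filter_low_intensity(m, min_mean = -Inf), m)
  expect_error(filter_low_intensity(m, min_mean = 100), "reduce min_mean")
  # default quantile rule drops the bottom quarter by mean
  big <- matrix(rep(1:8, each = 2), nrow = 8, byrow = TRUE,
                dimnames = list(paste0("g", 1:8), c("a", "b")))
  expect_identical(nrow(filter_low_intensity(big)), 6L)
})

test_that("quantile normalization equalizes column order statistics", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(out[, "a"], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(2.5, 3.5, 4.5), ignore_attr = TRUE)

  # rank order inside each column is preserved
  m2 <- cbind(a = c(3, 1, 2), b = c(40, 60, 50))
  out2 <- quantile_normalize(m2)
  expect_identical(order(out2[, "a"]), order(m2[, "a"]))
  expect_identical(order(out2[, "b"]), order(m2[, "b"]))

  # identical columns are a fixed point
  m3 <- cbind(a = c(1, 5, 2), b = c(1, 5, 2))
  expect_equal(quantile_normalize(m3), m3)

  # definitional postcondition on arbitrary input
  set.seed(31)
  m4 <- matrix(rnorm(60), 12, 5)
  out4 <- quantile_normalize(m4)
  sorted <- apply(out4, 2, sort)
  expect_equal(sorted, sorted[, c(2:5, 1)], ignore_attr = TRUE)

  expect_error(quantile_normalize(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("quantile normalization is idempotent and ties share spanned references", {
  set.seed(77)
  m <- matrix(rnorm(200), 40, 5)
  once <- quantile_normalize(m)
  expect_equal(quantile_normalize(once), once, tolerance = 1e-12)

  # ties: column (1, 1, 2) against (10, 20, 30); reference = (5.5, 10.5, 16)
  m2 <- cbind(a = c(1, 1, 2), b = c(10, 20, 30))
  out <- quantile_normalize(m2)
  expect_equal(unname(out[, "a"]), c(8, 8, 16))
  expect_equal(unname(out[, "b"]), c(5.5, 10.5, 16))
})

test_that("quantile normalization matches limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(19)
  m <- matrix(rnorm(300), 50, 6)
  expect_equal(quantile_normalize(m), limma::normalizeQuantiles(m),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("preprocessing composes probe averaging, filtering and normalization in order", {
  set.seed(4)
  m <- matrix(rnorm(40, mean = 5), nrow = 8, ncol = 5,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:5)))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gC", p5 = "gD",
           p6 = "gE", p7 = "gF", p8 = "gG")
  manual <- quantile_normalize(
    filter_low_intensity(average_duplicate_probes(m, map), min_mean_quantile = 0.25))
  expect_equal(preprocess_expression(m, probe_to_gene = map), manual)
})
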