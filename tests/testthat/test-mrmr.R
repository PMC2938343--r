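test_that("discretization thresholds at mean +/- t*sd", {
  expect_identical(discretize(c(1, 2, 3, 4, 5)), c(-1L, 0L, 0L, 0L, 1L))
  expect_identical(discretize(rep(2, 6)), rep(0L, 6))
  expect_identical(discretize(rnorm(50), t = 100), rep(0L, 50))
  # matrix version agrees with the vector version row by row
  set.seed(8)
  m <- matrix(rnorm(60), 6, 10)
  dm <- discretize_matrix(m, t = 0.7)
  for (i in 1:6) expect_identical(dm[i, ], discretize(m[i, ], t = 0.7))
})

test_that("mutual information matches hand values and the brute-force oracle", {
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_error(mutual_information(1:3, 1:4), "equal length")
  set.seed(21)
  for (i in 1:25) {
    cs <- random_mi_case()
    got <- mutual_information(cs$x, cs$y)
    expect_equal(got, oracle_mi(cs$x, cs$y))
    expect_gte(got, 0)
    expect_equal(got, mutual_information(cs$y, cs$x))
    expect_equal(mutual_information(cs$x, cs$x), oracle_entropy(cs$x))
  }
})

test_that("relevance and redundancy follow their definitions", {
  classes <- rep(group_levels(), each = 4)
  gene <- rep(1:4, each = 4)                  # gene identical to the label coding
  expect_equal(relevance(gene, classes), 2)   # entropy of a uniform 4-way variable
  indep <- rep(c(-1L, 1L), 8)
  expect_equal(relevance(indep, classes), 0)

  g <- c(-1L, -1L, 0L, 0L, 1L, 1L)
  expect_equal(redundancy(g, list(g)), oracle_entropy(g))
  expect_equal(redundancy(g, list()), 0)
  other <- c(1L, -1L, 1L, -1L, 1L, -1L)
  expect_equal(redundancy(g, list(other)), 0)
  third <- c(-1L, 0L, 0L, 1L, 1L, -1L)
  expect_equal(redundancy(g, list(g, third)),
               mean(c(oracle_mi(g, g), oracle_mi(g, third))))
})

test_that("the most relevant gene is ranked first", {
  groups <- rep(group_levels(), each = 3)
  # gene A discretizes to -1/0/0/+1 across the four groups; B, C are noise
  x <- rbind(
    A = rep(c(-10, 0, 0, 10), each = 3) + rep(c(0, 0.2, -0.2), 4),
    B = c(1, -2, 0.5, 0.3, -1, 2, 0.1, -0.4, 1.2, -0.6, 0.8, -1.5),
    C = c(0.4, 1.1, -0.2, -1.3, 0.6, 0.2, -0.9, 1.4, 0.3, -0.5, 0.7, -1.1)
  )
  colnames(x) <- sprintf("s%02d", 1:12)
  r <- rank_features(x, groups, n_select = 3)
  expect_identical(r$gene_id[1], "A")
  expect_equal(r$redundancy[1], 0)
  expect_equal(r$relevance[1], max(r$relevance))
})

test_that("a duplicated top gene is demoted below an informative independent gene", {
  # A and A2 identical and highly class-informative; B weaker but independent.
  # After picking A, the copy pays its full entropy as redundancy, so B goes
  # second whenever D(A2) - H(A) < D(B) - I(B, A).
  groups <- rep(group_levels(), each = 4)
  a <- rep(c(-10, 0, 0, 10), each = 4) + rep(c(0, .1, -.1, .2), 4)
  b <- rep(c(0, -10, 10, 0), each = 4) + rep(c(.1, -.1, 0, .2), 4)
  x <- rbind(A = a, A2 = a, B = b)
  colnames(x) <- sprintf("s%02d", 1:16)
  da <- discretize_matrix(x)
  rel_a2 <- oracle_mi(da["A2", ], groups)
  h_a <- oracle_entropy(da["A", ])
  rel_b <- oracle_mi(da["B", ], groups)
  red_b <- oracle_mi(da["B", ], da["A", ])
  expect_lt(rel_a2 - h_a, rel_b - red_b)      # the instance exercises the rule
  r <- rank_features(x, groups, n_select = 3)
  expect_identical(r$gene_id, c("A", "B", "A2"))
})

test_that("greedy ranking equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:10) {
    cs <- random_expression_case(n_genes = sample(4:8, 1),
                                 n_samples = sample(12:24, 1))
    disc <- discretize_matrix(cs$x)
    n_sel <- nrow(cs$x)
    want <- rownames(cs$x)[oracle_mrmr(disc, cs$groups, n_sel)]
    got <- rank_features(cs$x, cs$groups, n_select = n_sel)
    expect_identical(got$gene_id, want)
    # reported relevance/redundancy agree with the oracle's definitions
    expect_equal(got$relevance,
                 vapply(got$gene_id,
                        function(g) oracle_mi(disc[g, ], cs$groups), numeric(1)),
                 ignore_attr = TRUE)
  }
})

test_that("ranking is deterministic and unaffected by adding a constant gene", {
  set.seed(5)
  cs <- random_expression_case(n_genes = 6, n_samples = 20)
  r1 <- rank_features(cs$x, cs$groups, n_select = 6)
  r2 <- rank_features(cs$x, cs$groups, n_select = 6)
  expect_identical(r1, r2)
  x_aug <- rbind(cs$x, constant = rep(3, ncol(cs$x)))
  r3 <- rank_features(x_aug, cs$groups, n_select = 7)
  expect_identical(setdiff(r3$gene_id, "constant"), r1$gene_id)
})

test_that("MIQ scheme ranks by relevance/redundancy quotient", {
  set.seed(14)
  cs <- random_expression_case(n_genes = 6, n_samples = 20)
  disc <- discretize_matrix(cs$x)
  want <- rownames(cs$x)[oracle_mrmr(disc, cs$groups, 6, scheme = "MIQ")]
  got <- rank_features(cs$x, cs$groups, n_select = 6, scheme = "MIQ")
  expect_identical(got$gene_id, want)
})

test_that("mRMR recovers planted subtype genes from a 500-gene background", {
  d <- simulate_dataset(simulation_config(
    n_genes = 500, group_sizes = c(40, 40, 40, 40),
    n_subtype_genes = 20, n_survival_genes = 0, n_shared_genes = 0,
    effect_size = 2, seed = 1))
  r <- rank_features(d$expression, phenotype_groups(d$phenotype), n_select = 40)
  expect_gte(mean(d$truth$gene_id %in% r$gene_id[1:40]), 0.8)
})

test_that("rank_features rejects bad arguments", {
  cs <- random_expression_case()
  expect_error(rank_features(cs$x, cs$groups, n_select = 0), "positive")
  expect_error(rank_features(cs$x, cs$groups[-1]), "one label per sample")
})
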