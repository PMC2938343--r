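# Independent brute-force reference implementations used as oracles.
# They share no code with the package internals: plain loops and sums.

# plug-in mutual information, bits, by explicit double sum over level pairs
oracle_mi <- function(x, y) {
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  total <- 0
  for (a in ux) {
    for (b in uy) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        px <- sum(x == a) / n
        py <- sum(y == b) / n
        total <- total + pxy * log2(pxy / (px * py))
      }
    }
  }
  total
}

oracle_entropy <- function(x) oracle_mi(x, x)

# naive greedy mRMR on an already-discretized genes x samples matrix
oracle_mrmr <- function(disc, classes, n_select, scheme = "MID") {
  p <- nrow(disc)
  rel <- vapply(seq_len(p), function(i) oracle_mi(disc[i, ], classes), numeric(1))
  selected <- integer(0)
  for (step in seq_len(n_select)) {
    remaining <- setdiff(seq_len(p), selected)
    best <- NA_integer_
    best_score <- -Inf
    for (i in remaining) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) oracle_mi(disc[i, ], disc[s, ]), numeric(1)))
      }
      score <- if (scheme == "MID") rel[i] - red else rel[i] / max(red, .Machine$double.eps)
      if (score > best_score) {         # strict: ties keep the earlier index
        best_score <- score
        best <- i
      }
    }
    selected <- c(selected, best)
  }
  selected
}

oracle_cosine <- function(x, y) 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# leave-one-out 1-NN by explicit all-pairs loops
oracle_loocv <- function(x, groups) {
  n <- ncol(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    best_d <- Inf
    best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- oracle_cosine(x[, i], x[, j])
      if (d < best_d) {                 # strict: earliest index wins ties
        best_d <- d
        best_j <- j
      }
    }
    pred[i] <- as.character(groups)[best_j]
  }
  pred
}

# full IFS recomputation for every k, using the loop oracles and
# survival::survdiff as the independent log-rank reference
oracle_ifs <- function(x, genes, phenotype, k_max) {
  out <- data.frame(k = seq_len(k_max), subtype_accuracy = NA_real_,
                    logrank_stat = NA_real_, logrank_p = NA_real_)
  groups <- paste(phenotype$subtype, phenotype$status, sep = "-")
  for (k in seq_len(k_max)) {
    pred <- oracle_loocv(x[genes[seq_len(k)], , drop = FALSE], groups)
    pred_subtype <- sub("-.*$", "", pred)
    out$subtype_accuracy[k] <- mean(pred_subtype == phenotype$subtype)
    risk <- ifelse(grepl("dead$", pred), "high", "low")
    if (length(unique(risk)) < 2) {
      out$logrank_stat[k] <- 0
      out$logrank_p[k] <- 1
    } else {
      sd_fit <- survival::survdiff(
        survival::Surv(phenotype$time, phenotype$event) ~ risk)
      out$logrank_stat[k] <- sd_fit$chisq
      out$logrank_p[k] <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
    }
  }
  out
}

# random small instance generators used by the oracle-equivalence suites
random_mi_case <- function(n = 30) {
  list(x = sample(c(-1L, 0L, 1L), n, replace = TRUE),
       y = sample(c(-1L, 0L, 1L), n, replace = TRUE))
}

random_expression_case <- function(n_genes = 8, n_samples = 16) {
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  groups <- sample(group_levels(), n_samples, replace = TRUE)
  # every group present at least once keeps merges non-degenerate
  groups[seq_len(4)] <- group_levels()
  list(x = x, groups = groups)
}

random_phenotype <- function(groups) {
  n <- length(groups)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    subtype = sub("-.*$", "", groups),
    status = sub("^.*-", "", groups),
    time = round(rexp(n, rate = 0.2) + 0.05, 3),
    event = ifelse(grepl("dead$", groups), 1L,
                   sample(c(0L, 1L), n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}
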