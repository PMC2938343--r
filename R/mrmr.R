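#' Three-level discretization of an expression vector
#'
#' Maps each value to -1, 0 or +1 relative to `mean +/- t * sd` of the vector
#' (sample standard deviation, n - 1 denominator): values above the upper
#' threshold become +1, below the lower threshold -1, and 0 otherwise.
#' Mutual-information estimation downstream works on these categories.
#' A constant vector discretizes to all zeros.
#'
#' @param values numeric vector (length >= 2, finite).
#' @param t threshold multiplier (> 0, default 1).
#' @return integer vector over \{-1, 0, +1\}.
#' @examples
#' discretize(c(1, 2, 3, 4, 5))  # -1 0 0 0 1
#' @export
discretize <- function(values, t = 1) {
  stopifnot(length(values) >= 2L, all(is.finite(values)), t > 0)
  m <- mean(values)
  s <- stats::sd(values)
  as.integer(values > m + t * s) - as.integer(values < m - t * s)
}

#' Discretize every gene of an expression matrix
#'
#' Applies [discretize()] row-wise (per gene), vectorized.
#'
#' @param x numeric genes x samples matrix.
#' @param t threshold multiplier.
#' @return integer matrix over \{-1, 0, +1\}, same dimnames.
#' @export
discretize_matrix <- function(x, t = 1) {
  stopifnot(is.matrix(x), ncol(x) >= 2L, all(is.finite(x)), t > 0)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
  up <- m + t * s
  lo <- m - t * s
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  out[x > up] <- 1L
  out[x < lo] <- -1L
  out
}

#' Plug-in mutual information between two categorical vectors
#'
#' Empirical mutual information from the joint frequency table, in bits
#' (log base 2), with the 0 * log 0 = 0 convention. Accepts any discrete
#' codings (integers, characters, factors).
#'
#' @param x,y equal-length category vectors.
#' @return mutual information in bits (>= 0).
#' @examples
#' mutual_information(c(0, 1, 0, 1), c(0, 0, 1, 1))  # 0: empirically independent
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  joint <- table(x, y)
  n <- sum(joint)
  pxy <- joint / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  pos <- pxy > 0
  sum(pxy[pos] * log2(pxy[pos] / outer(px, py)[pos]))
}

# Mutual information of one coded vector against every column of a coded
# matrix, via indicator cross-products (one BLAS call per level pair).
# x: integer codes 1..kx; m: integer matrix, codes 1..km. Returns bits.
mi_profile <- function(x, m, kx = max(x), km = max(m)) {
  n <- length(x)
  stopifnot(nrow(m) == n)
  xind <- matrix(0, n, kx)
  xind[cbind(seq_len(n), x)] <- 1
  nx <- colSums(xind) / n
  mi <- numeric(ncol(m))
  for (l in seq_len(km)) {
    cl <- crossprod(xind, m == l) / n          # kx x genes joint probs at y = l
    pl <- colSums(m == l) / n                  # marginal P(y = l) per gene
    for (j in seq_len(kx)) {
      p <- cl[j, ]
      denom <- nx[j] * pl
      pos <- p > 0
      mi[pos] <- mi[pos] + p[pos] * log2(p[pos] / denom[pos])
    }
  }
  mi
}

#' Relevance of a gene to the class variable
#'
#' Mutual information (bits) between a discretized gene and the four-group
#' classification variable.
#'
#' @param gene discretized gene vector.
#' @param classes class labels (factor or vector), one per sample.
#' @return relevance in bits.
#' @export
relevance <- function(gene, classes) {
  mutual_information(gene, classes)
}

#' Redundancy of a gene with an already-selected feature set
#'
#' Arithmetic mean of the mutual information between `gene` and each selected
#' feature. Defined as 0 for an empty selected set, so the first greedy pick
#' is purely relevance-driven.
#'
#' @param gene discretized gene vector.
#' @param selected list of discretized feature vectors (possibly empty).
#' @return redundancy in bits.
#' @export
redundancy <- function(gene, selected) {
  if (length(selected) == 0L) return(0)
  mean(vapply(selected, function(s) mutual_information(gene, s), numeric(1L)))
}

#' Greedy mRMR feature ranking
#'
#' Ranks genes by the minimum-redundancy maximum-relevance criterion on
#' discretized expression. The first pick maximizes relevance (mutual
#' information with the four-group label); each subsequent pick maximizes, in
#' the difference scheme (`"MID"`), relevance minus the mean mutual
#' information with the already-selected features, or their quotient under
#' `"MIQ"`. Ties are broken by input gene order (first wins); the procedure is
#' fully deterministic.
#'
#' @param x numeric genes x samples expression matrix with gene rownames.
#' @param groups four-group labels (factor or character), one per sample.
#' @param n_select how many genes to rank (candidate pool size; default 500,
#'   capped at the number of genes).
#' @param t discretization threshold multiplier (see [discretize()]).
#' @param scheme `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return data.frame of class `"ranked_features"` with columns `rank`,
#'   `gene_id`, `relevance`, `redundancy`, `score` in greedy-selection order.
#' @export
rank_features <- function(x, groups, n_select = 500L, t = 1,
                          scheme = c("MID", "MIQ")) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (length(groups) != ncol(x)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  if (anyNA(groups)) stop("every sample needs a group label", call. = FALSE)
  n_select <- as.integer(n_select)
  if (n_select <= 0L) stop("n_select must be positive", call. = FALSE)
  n_select <- min(n_select, nrow(x))

  disc <- discretize_matrix(x, t = t)
  codes <- base::t(disc) + 2L                 # samples x genes, codes 1..3
  cls <- as.integer(factor(groups))
  kc <- max(cls)

  rel <- mi_profile(cls, codes, kx = kc, km = 3L)
  p <- nrow(x)
  selected <- integer(n_select)
  red_at_pick <- numeric(n_select)
  score_at_pick <- numeric(n_select)
  mi_sum <- numeric(p)                        # running sum of MI vs selected
  remaining <- rep(TRUE, p)

  for (step in seq_len(n_select)) {
    if (step == 1L) {
      red <- numeric(p)
    } else {
      red <- mi_sum / (step - 1L)
    }
    score <- if (scheme == "MID") rel - red else rel / pmax(red, .Machine$double.eps)
    score[!remaining] <- -Inf
    pick <- which.max(score)                  # ties -> lowest index
    selected[step] <- pick
    red_at_pick[step] <- red[pick]
    score_at_pick[step] <- score[pick]
    remaining[pick] <- FALSE
    if (step < n_select) {
      mi_sum <- mi_sum + mi_profile(codes[, pick], codes, kx = 3L, km = 3L)
    }
  }

  structure(
    data.frame(
      rank = seq_len(n_select),
      gene_id = rownames(x)[selected],
      relevance = rel[selected],
      redundancy = red_at_pick,
      score = score_at_pick,
      stringsAsFactors = FALSE
    ),
    class = c("ranked_features", "data.frame")
  )
}
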