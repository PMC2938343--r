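#' Cosine-derived distance between two vectors
#'
#' `D(x, y) = 1 - <x, y> / (||x|| ||y||)`, in `[0, 2]`. Symmetric, zero for a
#' vector against itself, undefined (an error) when either vector has zero
#' norm, and invariant to positive rescaling of either argument.
#'
#' @param x,y numeric vectors of equal length.
#' @return the dissimilarity.
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))   # 1
#' cosine_distance(c(1, 1), c(1, 0))   # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("empty vectors", call. = FALSE)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine distance undefined for a zero-norm vector",
                               call. = FALSE)
  1 - sum(x * y) / (nx * ny)
}

#' Classify one sample by its nearest training neighbour
#'
#' Assigns the query the group of the training sample at minimum
#' [cosine_distance()]. Ties are broken by the lowest training-sample index.
#'
#' @param query numeric feature vector.
#' @param train numeric features x samples training matrix.
#' @param groups group label per training sample.
#' @return the predicted group (same type as `groups` elements).
#' @export
predict_one <- function(query, train, groups) {
  stopifnot(is.matrix(train))
  if (ncol(train) < 1L) stop("empty training set", call. = FALSE)
  if (length(groups) != ncol(train)) stop("one group label per training sample",
                                          call. = FALSE)
  if (nrow(train) != length(query)) stop("query/training feature mismatch",
                                         call. = FALSE)
  qn <- sqrt(sum(query^2))
  tn <- sqrt(colSums(train^2))
  if (qn == 0 || any(tn == 0)) {
    stop("cosine distance undefined for a zero-norm vector", call. = FALSE)
  }
  d <- 1 - as.vector(crossprod(train, query)) / (tn * qn)
  groups[which.min(d)]
}

#' Leave-one-out cross-validated nearest-neighbour prediction
#'
#' Each sample is held out in turn and classified by [predict_one()] against
#' the remaining samples, on the supplied feature subset. The held-out sample
#' never participates in its own neighbour search.
#'
#' @param x numeric features x samples matrix (already restricted to the
#'   feature subset under evaluation).
#' @param groups group label per sample (factor or character).
#' @return data.frame of class `"prediction_table"` with columns `sample_id`,
#'   `true_group`, `predicted_group`, `feature_count`.
#' @export
loocv_predict <- function(x, groups) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  if (n < 2L) stop("leave-one-out needs >= 2 samples", call. = FALSE)
  if (nrow(x) < 1L) stop("at least one feature required", call. = FALSE)
  if (length(groups) != n) stop("one group label per sample", call. = FALSE)
  norms <- sqrt(colSums(x^2))
  if (any(norms == 0)) stop("cosine distance undefined for a zero-norm vector",
                            call. = FALSE)
  d <- 1 - crossprod(x) / tcrossprod(norms)
  diag(d) <- Inf                              # a sample is never its own neighbour
  pred <- vapply(seq_len(n), function(i) which.min(d[, i]), integer(1L))
  structure(
    data.frame(
      sample_id = if (is.null(colnames(x))) as.character(seq_len(n)) else colnames(x),
      true_group = as.character(groups),
      predicted_group = as.character(groups)[pred],
      feature_count = nrow(x),
      stringsAsFactors = FALSE
    ),
    class = c("prediction_table", "data.frame")
  )
}
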