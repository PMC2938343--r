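#' Merge four-group predictions into binary subtype labels
#'
#' Projects each four-group label (subtype-status) onto its subtype
#' coordinate: predicted ABC-dead and ABC-alive samples become ABC, predicted
#' GCB-dead and GCB-alive become GCB.
#'
#' @param groups four-group labels (character/factor) or a
#'   `"prediction_table"` (its `predicted_group` column is used).
#' @return character vector over \{ABC, GCB\}.
#' @export
merge_subtype <- function(groups) {
  g <- as.character(if (inherits(groups, "prediction_table")) groups$predicted_group
                    else groups)
  bad <- setdiff(unique(g), group_levels())
  if (length(bad) > 0L) stop("unknown group label(s): ", paste(bad, collapse = ", "),
                             call. = FALSE)
  sub("-.*$", "", g)
}

#' Merge four-group predictions into binary risk labels
#'
#' Dead-labelled predictions (ABC-dead, GCB-dead) become `high` risk;
#' alive-labelled predictions become `low` risk.
#'
#' @inheritParams merge_subtype
#' @return character vector over \{high, low\}.
#' @export
merge_risk <- function(groups) {
  g <- as.character(if (inherits(groups, "prediction_table")) groups$predicted_group
                    else groups)
  bad <- setdiff(unique(g), group_levels())
  if (length(bad) > 0L) stop("unknown group label(s): ", paste(bad, collapse = ", "),
                             call. = FALSE)
  ifelse(endsWith(g, "dead"), "high", "low")
}

#' Overall subtype classification accuracy
#'
#' The overall success rate: (correctly predicted ABC + correctly predicted
#' GCB) / total samples.
#'
#' @param predicted,truth equal-length binary subtype labels.
#' @return accuracy in `[0, 1]`.
#' @export
subtype_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(truth)) stop("length mismatch", call. = FALSE)
  mean(as.character(predicted) == as.character(truth))
}

#' Incremental feature selection over an mRMR-ranked gene list
#'
#' For every feature-set size `k` from 1 to `k_max`, restricts the expression
#' matrix to the top-`k` ranked genes, runs leave-one-out nearest-neighbour
#' prediction of the four groups, and scores the two merged binary tasks:
#' merged subtype accuracy, and the log-rank statistic comparing observed
#' survival of predicted-high vs predicted-low risk samples. The Gram matrix
#' behind the cosine distances is updated incrementally (rank-one per added
#' gene), so the full sweep costs O(k_max n^2).
#'
#' If at some `k` every sample is predicted into one risk class, that record
#' keeps `logrank_stat = 0`, `logrank_p = 1` and a warning is logged, so the
#' curve stays index-complete.
#'
#' @param x numeric genes x samples expression matrix with gene rownames.
#' @param ranked a `"ranked_features"` data.frame (or a character vector of
#'   gene ids in rank order).
#' @param phenotype phenotype data.frame with `subtype`, `status`, `time`,
#'   `event` columns (samples in the same order as `x`).
#' @param k_max largest feature count to evaluate (defaults to the full
#'   ranked list).
#' @return data.frame of class `"ifs_curve"` with one row per `k`:
#'   `k`, `subtype_accuracy`, `logrank_stat`, `logrank_p`, `neg_log10_p`.
#' @export
ifs_run <- function(x, ranked, phenotype, k_max = NULL) {
  genes <- if (is.character(ranked)) ranked else ranked$gene_id
  if (length(genes) == 0L) stop("ranked gene list is empty", call. = FALSE)
  if (!all(genes %in% rownames(x))) stop("ranked genes missing from the matrix",
                                         call. = FALSE)
  stopifnot(ncol(x) == nrow(phenotype))
  if (is.null(k_max)) k_max <- length(genes)
  k_max <- min(as.integer(k_max), length(genes))
  n <- ncol(x)
  groups <- as.character(phenotype_groups(phenotype))
  true_subtype <- phenotype$subtype
  time <- phenotype$time
  event <- phenotype$event

  gram <- matrix(0, n, n)
  acc <- stat <- pval <- numeric(k_max)
  for (k in seq_len(k_max)) {
    v <- x[genes[k], ]
    gram <- gram + tcrossprod(v)
    norms2 <- diag(gram)
    if (any(norms2 == 0)) {
      stop("cosine distance undefined for a zero-norm vector (k = ", k, ")",
           call. = FALSE)
    }
    d <- 1 - gram / sqrt(tcrossprod(norms2))
    diag(d) <- Inf
    pred_idx <- apply(d, 2L, which.min)       # first minimum: earliest index wins ties
    pred <- groups[pred_idx]

    acc[k] <- subtype_accuracy(merge_subtype(pred), true_subtype)
    risk <- merge_risk(pred)
    if (length(unique(risk)) < 2L) {
      warning("k = ", k, ": all samples predicted into one risk class; ",
              "recording log-rank p = 1", call. = FALSE)
      stat[k] <- 0
      pval[k] <- 1
    } else {
      hi <- risk == "high"
      lr <- logrank_test(time[hi], event[hi], time[!hi], event[!hi])
      stat[k] <- lr$statistic
      pval[k] <- lr$p_value
    }
  }
  structure(
    data.frame(k = seq_len(k_max), subtype_accuracy = acc,
               logrank_stat = stat, logrank_p = pval,
               neg_log10_p = -log10(pval)),
    class = c("ifs_curve", "data.frame")
  )
}

#' Choose a single signature balancing both tasks
#'
#' Formalizes the "top right corner" choice on the accuracy vs -log10(p)
#' plane: over the window `k < k_max`, both metrics are min-max normalized to
#' `[0, 1]` and summed with equal weight; the chosen size is the argmax of
#' the summed score, ties broken by the smallest `k`. A metric that is
#' constant over the window contributes nothing; if both are constant the
#' choice degenerates to `k = 1` with a warning.
#'
#' @param curve an `"ifs_curve"`.
#' @param ranked the `"ranked_features"` (or gene-id vector) the curve was
#'   built from.
#' @param k_max exclusive upper bound of the search window (default 100, the
#'   restriction to small signatures).
#' @param weights length-2 positive weights for (accuracy, -log10 p).
#' @return list of class `"signature_selection"`: `chosen_k`, `gene_ids`,
#'   `subtype_accuracy`, `logrank_stat`, `logrank_p`, `selection_window`.
#' @export
select_balanced <- function(curve, ranked, k_max = 100L, weights = c(1, 1)) {
  stopifnot(inherits(curve, "data.frame"), all(weights > 0), length(weights) == 2L)
  genes <- if (is.character(ranked)) ranked else ranked$gene_id
  win <- curve[curve$k < k_max, , drop = FALSE]
  if (nrow(win) == 0L) stop("the curve has no k below k_max", call. = FALSE)

  norm01 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  na <- norm01(win$subtype_accuracy)
  np <- norm01(win$neg_log10_p)
  if (all(na == 0) && all(np == 0)) {
    warning("both IFS metrics constant over the window; choosing k = 1",
            call. = FALSE)
  }
  score <- weights[1] * na + weights[2] * np
  best <- which.max(score)                    # first max -> smallest k
  chosen_k <- win$k[best]
  structure(
    list(chosen_k = chosen_k,
         gene_ids = genes[seq_len(chosen_k)],
         subtype_accuracy = win$subtype_accuracy[best],
         logrank_stat = win$logrank_stat[best],
         logrank_p = win$logrank_p[best],
         selection_window = c(1L, as.integer(k_max))),
    class = "signature_selection"
  )
}

#' @export
print.signature_selection <- function(x, ...) {
  cat(sprintf("Signature of %d genes (window k in [%d, %d))\n",
              x$chosen_k, x$selection_window[1], x$selection_window[2]))
  cat(sprintf("  subtype accuracy: %.4f\n", x$subtype_accuracy))
  cat(sprintf("  log-rank p:       %.3g\n", x$logrank_p))
  cat("  genes: ", paste(utils::head(x$gene_ids, 10), collapse = ", "),
      if (x$chosen_k > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}
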