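#' Read an expression matrix from TSV
#'
#' Expects the package dialect: UTF-8, tab-separated, a header row whose first
#' cell is `gene_id` followed by unique sample identifiers, then one row per
#' gene/probe with numeric values. Parse problems are reported with the
#' offending line number.
#'
#' @param path file path.
#' @return numeric genes x samples matrix with gene and sample dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("expression file has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop("line 1: header must contain at least one sample column",
                                call. = FALSE)
  sample_ids <- header[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0L) {
    stop("line 1: duplicated sample column(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  n <- length(sample_ids)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != n + 1L)) {
    bad <- which(widths != n + 1L)[1L]
    stop("line ", bad + 1L, ": expected ", n + 1L, " fields, found ", widths[bad],
         call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n))
  )
  vals <- matrix(vals, nrow = n)          # samples x genes at this point
  if (anyNA(vals)) {
    bad_gene <- which(colSums(is.na(vals)) > 0L)[1L]
    stop("line ", bad_gene + 1L, ": non-numeric expression value", call. = FALSE)
  }
  x <- t(vals)
  dimnames(x) <- list(gene_ids, sample_ids)
  x
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: values are printed with 17 significant
#' digits so that a write/read round trip reproduces the matrix exactly.
#'
#' @param x numeric matrix with gene/sample dimnames.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' TSV with columns `sample_id`, `subtype` (ABC/GCB), `status` (dead/alive),
#' `time` (> 0) and `event` (0/1). Reading validates the enums, uniqueness of
#' sample ids, positivity of times and the consistency rule
#' `status == "dead"` implies `event == 1`; a derived `group` column
#' (subtype-status) is added.
#'
#' @param path file path.
#' @return data.frame with the five columns plus `group`.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subtype", "status", "time", "event")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols) > 0L) {
    stop("phenotype file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ph$sample_id)) stop("duplicated sample_id in phenotype table",
                                        call. = FALSE)
  if (!all(ph$subtype %in% c("ABC", "GCB"))) stop("subtype must be ABC or GCB",
                                                  call. = FALSE)
  if (!all(ph$status %in% c("dead", "alive"))) stop("status must be dead or alive",
                                                    call. = FALSE)
  if (!is.numeric(ph$time) || any(!is.finite(ph$time)) || any(ph$time <= 0)) {
    stop("time must be finite and > 0", call. = FALSE)
  }
  if (!all(ph$event %in% c(0L, 1L))) stop("event must be 0 or 1", call. = FALSE)
  if (any(ph$status == "dead" & ph$event != 1L)) {
    stop("status 'dead' requires event = 1", call. = FALSE)
  }
  ph$group <- as.character(phenotype_groups(ph))
  ph[c(need, "group")]
}

#' @rdname read_phenotype
#' @param phenotype data.frame with the phenotype columns.
#' @export
write_phenotype <- function(phenotype, path) {
  cols <- c("sample_id", "subtype", "status", "time", "event")
  stopifnot(all(cols %in% names(phenotype)))
  out <- phenotype[cols]
  out$time <- sprintf("%.17g", out$time)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average duplicate probes to genes
#'
#' Collapses a probes x samples matrix to genes x samples: each output row is
#' the arithmetic mean of all probe rows mapping to that gene. Probes without
#' a mapping are dropped. Gene order follows the first occurrence of each gene
#' among the input probes.
#'
#' @param x numeric probes x samples matrix with probe rownames.
#' @param probe_to_gene named character vector: names are probe ids, values
#'   gene ids. Each probe maps to at most one gene.
#' @return numeric genes x samples matrix with unique gene rownames.
#' @examples
#' m <- matrix(c(1, 3, 3, 5), nrow = 2, byrow = FALSE,
#'             dimnames = list(c("p1", "p2"), c("a", "b")))
#' average_duplicate_probes(m, c(p1 = "geneA", p2 = "geneA"))
#' @export
average_duplicate_probes <- function(x, probe_to_gene) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping", call. = FALSE)
  if (is.null(names(probe_to_gene))) stop("probe_to_gene must be named by probe id",
                                          call. = FALSE)
  if (anyDuplicated(names(probe_to_gene))) {
    stop("a probe maps to more than one gene", call. = FALSE)
  }
  keep <- rownames(x) %in% names(probe_to_gene)
  if (!any(keep)) stop("no probe in the matrix has a gene mapping", call. = FALSE)
  xm <- x[keep, , drop = FALSE]
  genes <- unname(probe_to_gene[rownames(xm)])
  first_seen <- unique(genes)
  sums <- rowsum(xm, group = genes, reorder = FALSE)
  counts <- as.vector(table(factor(genes, levels = rownames(sums))))
  out <- sums / counts
  out[first_seen, , drop = FALSE]
}

#' Filter low-intensity genes
#'
#' Keeps exactly the genes whose across-sample mean is at least `min_mean`;
#' row order is preserved. When `min_mean` is `NULL` the threshold is the
#' `min_mean_quantile` quantile of the per-gene means (default: drop the
#' bottom 25 percent of genes by mean intensity).
#'
#' @param x numeric genes x samples matrix.
#' @param min_mean absolute mean-intensity threshold, or `NULL` to use the
#'   quantile rule.
#' @param min_mean_quantile quantile of per-gene means used when `min_mean`
#'   is `NULL`.
#' @return the filtered matrix.
#' @export
filter_low_intensity <- function(x, min_mean = NULL, min_mean_quantile = 0.25) {
  stopifnot(is.matrix(x))
  means <- rowMeans(x)
  if (is.null(min_mean)) {
    stopifnot(min_mean_quantile >= 0, min_mean_quantile <= 1)
    min_mean <- stats::quantile(means, min_mean_quantile, names = FALSE, type = 7)
  }
  if (is.na(min_mean) || (!is.finite(min_mean) && min_mean > 0)) {
    stop("min_mean must be finite or -Inf", call. = FALSE)
  }
  keep <- means >= min_mean
  if (!any(keep)) {
    stop("low-intensity filter removed every gene; reduce min_mean (",
         format(min_mean), ")", call. = FALSE)
  }
  x[keep, , drop = FALSE]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same distribution: the reference
#' is the across-sample mean of the order statistics, and each value is
#' replaced by the reference value at its within-column rank. Ties within a
#' column receive the mean of the reference values their ranks span. Gene and
#' sample order are preserved; the transform is idempotent.
#'
#' @param x numeric genes x samples matrix with >= 2 samples.
#' @return the normalized matrix.
#' @examples
#' m <- cbind(a = c(3, 1, 2), b = c(6, 4, 5))
#' quantile_normalize(m)  # both columns become 2.5, 3.5, 4.5 in rank order
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 2L) stop("quantile normalization requires >= 2 samples", call. = FALSE)
  if (anyNA(x)) stop("missing values in expression matrix", call. = FALSE)
  ref <- rowMeans(apply(x, 2L, sort, method = "radix"))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "first")
    v <- ref[r]
    # tied values share the mean of the reference values they span
    out[, j] <- stats::ave(v, match(x[, j], x[, j]), FUN = mean)
  }
  out
}

#' Run the three preprocessing steps in order
#'
#' Probe averaging (optional), low-intensity filtering, quantile
#' normalization — in exactly that order.
#'
#' @param x probes/genes x samples matrix.
#' @param probe_to_gene optional named probe-to-gene map; `NULL` skips
#'   averaging (rows already genes).
#' @inheritParams filter_low_intensity
#' @param verbose print gene counts before/after each step.
#' @return the preprocessed genes x samples matrix.
#' @export
preprocess_expression <- function(x, probe_to_gene = NULL, min_mean = NULL,
                                  min_mean_quantile = 0.25, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("input: ", nrow(x), " rows x ", ncol(x), " samples")
  if (!is.null(probe_to_gene)) {
    x <- average_duplicate_probes(x, probe_to_gene)
    say("after probe averaging: ", nrow(x), " genes")
  }
  x <- filter_low_intensity(x, min_mean = min_mean,
                            min_mean_quantile = min_mean_quantile)
  say("after low-intensity filter: ", nrow(x), " genes")
  x <- quantile_normalize(x)
  say("after quantile normalization: ", nrow(x), " genes")
  x
}
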