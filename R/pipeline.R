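#' Configuration for a full signature-selection run
#'
#' Validates and bundles all run parameters: either a simulation config (the
#' run generates its own data) or paths to an expression TSV and phenotype
#' TSV, plus preprocessing, ranking and selection parameters.
#'
#' @param out_dir output directory for all artifacts.
#' @param sim a [simulation_config()], or `NULL` to read data from files.
#' @param expression_path,phenotype_path input TSVs (used when `sim` is NULL).
#' @param preprocess logical; run low-intensity filtering + quantile
#'   normalization before ranking.
#' @param probe_to_gene optional named probe-to-gene map for duplicate-probe
#'   averaging.
#' @param min_mean,min_mean_quantile see [filter_low_intensity()].
#' @param disc_t discretization threshold multiplier (see [discretize()]).
#' @param scheme mRMR combination scheme, `"MID"` or `"MIQ"`.
#' @param n_select size of the mRMR candidate pool.
#' @param k_max exclusive upper bound of the signature-size search window.
#' @param weights selection weights, see [select_balanced()].
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(),
                            expression_path = NULL,
                            phenotype_path = NULL,
                            preprocess = TRUE,
                            probe_to_gene = NULL,
                            min_mean = NULL,
                            min_mean_quantile = 0.25,
                            disc_t = 1,
                            scheme = c("MID", "MIQ"),
                            n_select = 500L,
                            k_max = 100L,
                            weights = c(1, 1)) {
  scheme <- match.arg(scheme)
  if (is.null(sim)) {
    if (is.null(expression_path) || is.null(phenotype_path)) {
      stop("without a simulation config, expression_path and phenotype_path are required",
           call. = FALSE)
    }
    if (!file.exists(expression_path)) {
      stop("expression file not found: ", expression_path, call. = FALSE)
    }
    if (!file.exists(phenotype_path)) {
      stop("phenotype file not found: ", phenotype_path, call. = FALSE)
    }
  } else {
    validate_simulation_config(sim)
  }
  stopifnot(n_select >= 1L, k_max >= 2L, length(weights) == 2L, all(weights > 0))
  structure(
    list(out_dir = out_dir, sim = sim,
         expression_path = expression_path, phenotype_path = phenotype_path,
         preprocess = isTRUE(preprocess), probe_to_gene = probe_to_gene,
         min_mean = min_mean, min_mean_quantile = min_mean_quantile,
         disc_t = disc_t, scheme = scheme,
         n_select = as.integer(n_select), k_max = as.integer(k_max),
         weights = weights),
    class = "pipeline_config"
  )
}

#' Run the full signature-selection pipeline
#'
#' Executes, in order: data acquisition (simulation or file input),
#' preprocessing (low-intensity filter + quantile normalization), mRMR
#' ranking, the IFS sweep, balanced signature selection, and Kaplan-Meier /
#' log-rank evaluation of the selected signature's predicted risk groups.
#' Every intermediate artifact is written under `config$out_dir` and a JSON
#' report summarizes the run. Identical config (including the simulation
#' seed) reproduces every output file byte-identically.
#'
#' On a stage failure the run aborts naming the stage, and a `MANIFEST` file
#' in the output directory records which artifacts were completed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report as a list (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  note <- function(path) manifest <<- c(manifest, basename(path))
  fail <- function(stage, err) {
    writeLines(c(manifest, paste0("INCOMPLETE: failed at stage '", stage, "'")),
               file.path(config$out_dir, "MANIFEST"))
    stop("stage '", stage, "' failed: ", conditionMessage(err), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  # -- data ------------------------------------------------------------
  dat <- stage("data", {
    if (!is.null(config$sim)) {
      d <- simulate_dataset(config$sim)
      paths <- write_dataset(d, config$out_dir)
      for (p in paths) note(p)
      list(expression = d$expression, phenotype = d$phenotype, truth = d$truth)
    } else {
      list(expression = read_expression(config$expression_path),
           phenotype = read_phenotype(config$phenotype_path),
           truth = NULL)
    }
  })
  ph <- dat$phenotype
  if (!identical(colnames(dat$expression), ph$sample_id)) {
    stage("data", stop("expression sample ids do not match the phenotype table"))
  }

  # -- preprocess ------------------------------------------------------
  x <- stage("preprocess", {
    if (config$preprocess) {
      m <- preprocess_expression(dat$expression,
                                 probe_to_gene = config$probe_to_gene,
                                 min_mean = config$min_mean,
                                 min_mean_quantile = config$min_mean_quantile)
      p <- file.path(config$out_dir, "expression_preprocessed.tsv")
      write_expression(m, p); note(p)
      m
    } else {
      dat$expression
    }
  })

  # -- rank ------------------------------------------------------------
  groups <- phenotype_groups(ph)
  ranked <- stage("rank", {
    r <- rank_features(x, groups, n_select = config$n_select,
                       t = config$disc_t, scheme = config$scheme)
    p <- file.path(config$out_dir, "ranked_features.tsv")
    utils::write.table(format(r, digits = 12), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(p)
    r
  })

  # -- ifs -------------------------------------------------------------
  curve <- stage("ifs", {
    cv <- ifs_run(x, ranked, ph, k_max = min(config$k_max, nrow(ranked)))
    p <- file.path(config$out_dir, "ifs_curve.tsv")
    utils::write.table(format(cv, digits = 12), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(p)
    cv
  })

  # -- select ----------------------------------------------------------
  sel <- stage("select", {
    s <- select_balanced(curve, ranked, k_max = config$k_max,
                         weights = config$weights)
    p <- file.path(config$out_dir, "signature.tsv")
    utils::write.table(
      data.frame(rank = seq_len(s$chosen_k), gene_id = s$gene_ids),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p)
    s
  })

  # -- survival --------------------------------------------------------
  surv <- stage("survival", {
    pred <- loocv_predict(x[sel$gene_ids, , drop = FALSE], groups)
    pp <- file.path(config$out_dir, "predictions.tsv")
    utils::write.table(pred, pp, sep = "\t", quote = FALSE, row.names = FALSE)
    note(pp)
    risk <- merge_risk(pred)
    out <- list(risk = risk)
    for (cls in c("high", "low")) {
      idx <- risk == cls
      if (any(idx)) {
        km <- km_estimate(ph$time[idx], ph$event[idx])
        kp <- file.path(config$out_dir, paste0("km_", cls, ".tsv"))
        utils::write.table(format(km_table(km), digits = 12), kp, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        note(kp)
        out[[cls]] <- km
      }
    }
    out
  })

  # -- report ----------------------------------------------------------
  report <- list(
    seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
    n_samples = ncol(x),
    n_genes = nrow(x),
    n_select = nrow(ranked),
    k_max = config$k_max,
    chosen_k = sel$chosen_k,
    gene_ids = sel$gene_ids,
    subtype_accuracy = sel$subtype_accuracy,
    logrank_stat = sel$logrank_stat,
    logrank_p = sel$logrank_p
  )
  rp <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note(rp)
  writeLines(manifest, file.path(config$out_dir, "MANIFEST"))
  invisible(report)
}
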