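#' Simulation configuration for the four-group expression/survival generator
#'
#' Bundles and validates every knob of [simulate_dataset()]. The generator
#' emulates a bulk expression study of two tumour subtypes (ABC, GCB) crossed
#' with vital status (dead, alive), i.e. four patient groups, with a
#' configurable number of genes carrying a subtype and/or survival mean shift
#' on top of Gaussian noise, and exponentially distributed survival times under
#' uniform administrative censoring.
#'
#' Default group sizes follow the 94:73:49:134 split
#' (ABC-dead, ABC-alive, GCB-dead, GCB-alive) of the motivating lymphoma
#' cohort, scaled down to 88 patients.
#'
#' @param n_genes total number of genes.
#' @param group_sizes integer vector of length 4: number of samples in the
#'   ABC-dead, ABC-alive, GCB-dead and GCB-alive groups, in that order.
#' @param n_subtype_genes genes whose mean is shifted by `effect_size` in GCB
#'   samples only.
#' @param n_survival_genes genes shifted by `effect_size` in alive samples only.
#' @param n_shared_genes genes shifted on both axes (additively).
#' @param effect_size standardized mean difference added to informative genes.
#' @param noise_sd per-gene Gaussian noise standard deviation.
#' @param baseline_hazard exponential event rate (events per time unit) for the
#'   alive-labelled (low-risk) groups.
#' @param hazard_ratio multiplicative hazard for the dead-labelled groups
#'   (must be >= 1).
#' @param censor_time_max administrative censoring horizon; each sample draws
#'   an independent Uniform(0, censor_time_max) censoring time.
#' @param seed integer seed; generation is a pure function of it.
#' @return a list of class `"simulation_config"`.
#' @seealso [simulate_dataset()]
#' @export
simulation_config <- function(n_genes = 500L,
                              group_sizes = c(24L, 18L, 12L, 34L),
                              n_subtype_genes = 10L,
                              n_survival_genes = 10L,
                              n_shared_genes = 0L,
                              effect_size = 2,
                              noise_sd = 1,
                              baseline_hazard = 0.1,
                              hazard_ratio = 3,
                              censor_time_max = 10,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    group_sizes = as.integer(group_sizes),
    n_subtype_genes = as.integer(n_subtype_genes),
    n_survival_genes = as.integer(n_survival_genes),
    n_shared_genes = as.integer(n_shared_genes),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    baseline_hazard = as.numeric(baseline_hazard),
    hazard_ratio = as.numeric(hazard_ratio),
    censor_time_max = as.numeric(censor_time_max),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop("invalid simulation config: field '", field, "' ", msg, call. = FALSE)
  }
  counts <- c("n_genes", "n_subtype_genes", "n_survival_genes", "n_shared_genes")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L) stop_field(f, "must be a single count >= 0")
  }
  if (cfg$n_genes < 1L) stop_field("n_genes", "must be >= 1")
  gs <- cfg$group_sizes
  if (length(gs) != 4L || anyNA(gs) || any(gs < 1L)) {
    stop_field("group_sizes", "must be four positive counts")
  }
  if (sum(gs) < 8L) stop_field("group_sizes", "must sum to >= 8 (>= 2 per group)")
  n_inf <- cfg$n_subtype_genes + cfg$n_survival_genes + cfg$n_shared_genes
  if (n_inf > cfg$n_genes) {
    stop_field("n_subtype_genes", paste0(
      "+ n_survival_genes + n_shared_genes (", n_inf,
      ") must not exceed n_genes (", cfg$n_genes, ")"))
  }
  if (is.na(cfg$effect_size) || cfg$effect_size < 0) stop_field("effect_size", "must be >= 0")
  if (is.na(cfg$noise_sd) || cfg$noise_sd <= 0) stop_field("noise_sd", "must be > 0")
  if (is.na(cfg$baseline_hazard) || cfg$baseline_hazard <= 0) {
    stop_field("baseline_hazard", "must be > 0")
  }
  if (is.na(cfg$hazard_ratio) || cfg$hazard_ratio < 1) stop_field("hazard_ratio", "must be >= 1")
  if (is.na(cfg$censor_time_max) || cfg$censor_time_max <= 0) {
    stop_field("censor_time_max", "must be > 0")
  }
  if (is.na(cfg$seed)) stop_field("seed", "must be a finite integer")
  invisible(cfg)
}

#' The four patient group labels, in canonical order
#'
#' The cross of subtype (ABC, GCB) and vital status (dead, alive); the
#' classification variable of the four-group nearest-neighbour model.
#' @return character vector of length 4.
#' @export
group_levels <- function() {
  c("ABC-dead", "ABC-alive", "GCB-dead", "GCB-alive")
}

#' Simulate a four-group expression and survival dataset
#'
#' Draws a genes x samples expression matrix as Gaussian noise
#' (mean 0, sd `noise_sd`) plus `effect_size` added to subtype-informative
#' genes in GCB samples and to survival-informative genes in alive samples
#' (shared genes receive both shifts). Survival times are exponential with
#' rate `baseline_hazard` for alive-labelled samples and
#' `baseline_hazard * hazard_ratio` for dead-labelled samples, censored at an
#' independent Uniform(0, `censor_time_max`) draw; `event = 1` iff the event
#' time falls before the censoring time. Dead-labelled samples are forced to
#' an observed event (`event = 1`) by redrawing their event time until it
#' precedes their censoring time, so the vital-status label is consistent
#' with the event column.
#'
#' The function is a pure function of `config$seed`: it saves and restores the
#' caller's RNG state and two calls with the same config are byte-identical.
#'
#' @param config a [simulation_config()].
#' @return a list of class `"synthetic_dataset"` with elements
#'   \describe{
#'     \item{expression}{numeric genes x samples matrix with gene/sample
#'       dimnames.}
#'     \item{phenotype}{data.frame with columns `sample_id`, `subtype`
#'       (ABC/GCB), `status` (dead/alive), `time`, `event` and the derived
#'       four-level `group`.}
#'     \item{truth}{data.frame with columns `gene_id` and `axis`
#'       (subtype / survival / both) flagging the informative genes.}
#'     \item{config}{the config used.}
#'   }
#' @examples
#' d <- simulate_dataset(simulation_config(n_genes = 20,
#'                                         group_sizes = c(3, 3, 3, 3),
#'                                         seed = 7))
#' dim(d$expression)
#' table(d$phenotype$group)
#' @export
simulate_dataset <- function(config = simulation_config()) {
  validate_simulation_config(config)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  gs <- config$group_sizes
  n <- sum(gs)
  p <- config$n_genes
  group <- factor(rep(group_levels(), times = gs), levels = group_levels())
  subtype <- factor(sub("-.*$", "", group), levels = c("ABC", "GCB"))
  status <- factor(sub("^.*-", "", group), levels = c("dead", "alive"))

  gene_ids <- sprintf("g%04d", seq_len(p))
  sample_ids <- sprintf("s%03d", seq_len(n))

  x <- matrix(stats::rnorm(p * n, mean = 0, sd = config$noise_sd),
              nrow = p, ncol = n, dimnames = list(gene_ids, sample_ids))

  n_sub <- config$n_subtype_genes
  n_sur <- config$n_survival_genes
  n_sha <- config$n_shared_genes
  idx_sub <- seq_len(n_sub)
  idx_sur <- seq_len(n_sur) + n_sub
  idx_sha <- seq_len(n_sha) + n_sub + n_sur
  is_gcb <- subtype == "GCB"
  is_alive <- status == "alive"
  e <- config$effect_size
  if (n_sub > 0L && any(is_gcb)) x[idx_sub, is_gcb] <- x[idx_sub, is_gcb] + e
  if (n_sur > 0L && any(is_alive)) x[idx_sur, is_alive] <- x[idx_sur, is_alive] + e
  if (n_sha > 0L) {
    if (any(is_gcb)) x[idx_sha, is_gcb] <- x[idx_sha, is_gcb] + e
    if (any(is_alive)) x[idx_sha, is_alive] <- x[idx_sha, is_alive] + e
  }

  rate <- ifelse(status == "dead",
                 config$baseline_hazard * config$hazard_ratio,
                 config$baseline_hazard)
  event_time <- stats::rexp(n, rate = rate)
  censor_time <- stats::runif(n, min = 0, max = config$censor_time_max)
  # dead-labelled samples must show an observed event: redraw until uncensored
  dead <- which(status == "dead")
  repeat {
    bad <- dead[event_time[dead] > censor_time[dead]]
    if (length(bad) == 0L) break
    event_time[bad] <- stats::rexp(length(bad), rate = rate[bad])
  }
  event <- as.integer(event_time <= censor_time)
  time <- pmin(event_time, censor_time)

  truth_axis <- c(rep("subtype", n_sub), rep("survival", n_sur), rep("both", n_sha))
  truth <- data.frame(
    gene_id = gene_ids[seq_len(n_sub + n_sur + n_sha)],
    axis = truth_axis,
    stringsAsFactors = FALSE
  )

  phenotype <- data.frame(
    sample_id = sample_ids,
    subtype = as.character(subtype),
    status = as.character(status),
    time = time,
    event = event,
    group = as.character(group),
    stringsAsFactors = FALSE
  )

  structure(
    list(expression = x, phenotype = phenotype, truth = truth, config = config),
    class = "synthetic_dataset"
  )
}

#' Derive the four-group label from a phenotype table
#'
#' @param phenotype data.frame with `subtype` and `status` columns.
#' @return factor with levels [group_levels()].
#' @export
phenotype_groups <- function(phenotype) {
  stopifnot(all(c("subtype", "status") %in% names(phenotype)))
  g <- paste(phenotype$subtype, phenotype$status, sep = "-")
  bad <- setdiff(unique(g), group_levels())
  if (length(bad) > 0L) {
    stop("phenotype rows outside the four groups: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(g, levels = group_levels())
}

#' Write a synthetic dataset to TSV files
#'
#' Writes the expression matrix and phenotype table in the package TSV
#' dialects (see [write_expression()], [write_phenotype()]) plus a truth table
#' (`gene_id`, `axis`).
#'
#' @param dataset a `"synthetic_dataset"`.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression(dataset$expression, paths[["expression"]])
  write_phenotype(dataset$phenotype, paths[["phenotype"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
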