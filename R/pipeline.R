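#' Configure a knockdown-analysis run
#'
#' Collects everything the pipeline stages need: input/output paths, the
#' target feature, the reference arm, a single top-level seed that drives
#' every source of randomness, and optional stage switches. A config can be
#' built in code or loaded from YAML ([read_run_config()]); every file the
#' pipeline writes embeds the config hash, the seed and the package
#' version, so reruns with an identical config are byte-identical.
#'
#' @param out_dir directory all outputs are written under.
#' @param counts_dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (written there by [run_simulate()] when the config
#'   carries a `cohort` block).
#' @param annotations path to the annotation TSV.
#' @param target_feature feature id of the target gene.
#' @param reference_treatment control-arm label.
#' @param seed integer seed for all randomness.
#' @param run_modes run the single-cell architecture comparison stage.
#' @param modes_cell_type cell type for the comparison (default: the most
#'   abundant).
#' @param cohort optional named list of [cohort_spec()] arguments; when
#'   present [run_simulate()] can generate the inputs.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       counts_dir = file.path(out_dir, "cohort"),
                       annotations = file.path(counts_dir, "annotations.tsv"),
                       target_feature = "TARGET",
                       reference_treatment = "control",
                       seed = 1L,
                       run_modes = TRUE,
                       modes_cell_type = NULL,
                       cohort = NULL) {
  check_count(seed, "seed", lower = 0L)
  structure(list(out_dir = out_dir, counts_dir = counts_dir,
                 annotations = annotations,
                 target_feature = target_feature,
                 reference_treatment = reference_treatment,
                 seed = as.integer(seed), run_modes = isTRUE(run_modes),
                 modes_cell_type = modes_cell_type, cohort = cohort),
            class = "run_config")
}

#' @param path YAML file with `run_config()` fields.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_bad("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$out_dir)) stop_bad("config needs an out_dir")
  do.call(run_config, raw)
}

# polynomial rolling hash over the canonical JSON form (double arithmetic,
# modulus below 2^31); identifies a config in output headers
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

run_meta <- function(config) {
  list(config_hash = config_hash(config), seed = config$seed,
       asokd_version = as.character(packageVersion("asokd")))
}

as_cohort_spec <- function(x, seed) {
  if (inherits(x, "cohort_spec")) return(x)
  if (!is.list(x)) stop_bad("cohort block must be a list of cohort_spec args")
  if (!is.null(x$cell_types))
    x$cell_types <- lapply(x$cell_types, function(ct)
      do.call(cell_type_spec, ct))
  if (is.null(x$seed)) x$seed <- seed
  do.call(cohort_spec, x)
}

#' Pipeline stages: simulate, aggregate, fit, modes, summarize
#'
#' Thin orchestration over the package's analysis functions. Each stage
#' reads its inputs from disk (or from the previous stage's output paths),
#' writes its outputs under `config$out_dir`, and embeds the config hash,
#' seed and package version in every file. [run_all()] chains the stages.
#'
#' * `run_simulate()` generates the synthetic cohort described by
#'   `config$cohort` and writes it to `config$counts_dir`.
#' * `run_aggregate()` reads the counts + annotations and writes the
#'   pseudobulk table (`pseudobulk.tsv`).
#' * `run_fit()` fits the NB offset model; writes `estimates.tsv`
#'   (percent scale), `per_animal.tsv` and `fit_report.json`.
#' * `run_modes()` fits the control NB for one cell type and compares the
#'   two knockdown architectures at the pseudobulk residual; writes
#'   `mode_report.json` and `histogram.tsv`.
#' * `run_summarize()` writes the difference-from-overall profile
#'   (`profile.tsv`, with the overall residual from the all-cells
#'   aggregate), the weighted SD across cell types, and pairwise weighted
#'   correlations between treatment profiles (`summary.json`,
#'   `correlations.tsv`).
#'
#' @param config a [run_config()].
#' @return each stage invisibly returns a named list of the paths it
#'   wrote; `run_all()` returns the union.
#' @export
run_simulate <- function(config) {
  if (is.null(config$cohort))
    stop_bad("config has no cohort block to simulate from")
  spec <- as_cohort_spec(config$cohort, config$seed)
  cohort <- generate_cohort(spec)
  paths <- write_cohort(cohort, config$counts_dir)
  meta_path <- file.path(config$counts_dir, "run_meta.yaml")
  yaml::write_yaml(run_meta(config), meta_path)
  invisible(c(paths, list(meta = meta_path)))
}

load_inputs <- function(config) {
  m <- read_counts(file.path(config$counts_dir, "matrix.mtx"),
                   file.path(config$counts_dir, "features.tsv"),
                   file.path(config$counts_dir, "barcodes.tsv"))
  ann <- read_annotations(config$annotations)
  list(counts = m, annotations = ann)
}

#' @rdname run_simulate
#' @export
run_aggregate <- function(config) {
  inp <- load_inputs(config)
  if (!config$target_feature %in% rownames(inp$counts))
    stop_bad("target feature '", config$target_feature,
             "' not present in counts")
  pb <- aggregate_pseudobulk(inp$counts, inp$annotations,
                             config$target_feature)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, "pseudobulk.tsv")
  write_pseudobulk(pb, path, meta = run_meta(config))
  invisible(list(pseudobulk = path))
}

#' @rdname run_simulate
#' @export
run_fit <- function(config) {
  pb_path <- file.path(config$out_dir, "pseudobulk.tsv")
  if (!file.exists(pb_path)) run_aggregate(config)
  pb <- read_pseudobulk(pb_path)
  design <- design_spec(pb, config$reference_treatment)
  fit <- fit_nb_offset_model(pb, design)
  meta <- run_meta(config)
  paths <- list(estimates = file.path(config$out_dir, "estimates.tsv"),
                per_animal = file.path(config$out_dir, "per_animal.tsv"),
                report = file.path(config$out_dir, "fit_report.json"))

  has_treated <- length(setdiff(design$treatments,
                                design$reference_treatment)) > 0
  if (has_treated) {
    est <- residual_fractions(fit, design)
    est$residual <- est$residual * 100
    est$ci_low <- est$ci_low * 100
    est$ci_high <- est$ci_high * 100
    pa <- per_animal_estimates(fit, design)
    pa$residual <- pa$residual * 100
  } else {
    # control-only input: report baseline rates, no residuals
    base <- fit$beta[paste0("ct:", design$cell_types)]
    est <- data.frame(cell_type = design$cell_types, treatment = NA,
                      residual = NA, ci_low = NA, ci_high = NA,
                      n_cells = NA, flag = "control_only",
                      baseline_rate = exp(base), stringsAsFactors = FALSE)
    pa <- est[0, ]
  }
  con <- file(paths$estimates, "w"); write_meta_header(con, meta)
  write.table(est, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- file(paths$per_animal, "w"); write_meta_header(con, meta)
  write.table(pa, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(meta = meta,
         beta = as.list(fit$beta), se = as.list(fit$se),
         theta = fit$theta, loglik = fit$loglik,
         converged = fit$converged, n_iter = fit$n_iter,
         flags = as.list(fit$flags[fit$flags != ""])),
    paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname run_simulate
#' @param r residual fraction for the architecture comparison; default:
#'   the pseudobulk estimate for the chosen cell type.
#' @export
run_modes <- function(config, r = NULL) {
  inp <- load_inputs(config)
  ann <- inp$annotations
  ct <- config$modes_cell_type %||%
    names(sort(table(ann$cell_type), decreasing = TRUE))[1L]
  if (!ct %in% ann$cell_type) stop_bad("cell type '", ct, "' not present")
  ctl <- per_cell_target_counts(inp$counts, ann, config$target_feature, ct,
                                treatment = config$reference_treatment)
  trt_labels <- setdiff(unique(ann$treatment), config$reference_treatment)
  if (!length(trt_labels)) stop_bad("no treated arm for mode comparison")
  trt <- per_cell_target_counts(inp$counts, ann, config$target_feature, ct,
                                treatment = trt_labels[1L])
  control_model <- fit_control_nb(ctl)
  if (is.null(r)) {
    est_path <- file.path(config$out_dir, "estimates.tsv")
    if (!file.exists(est_path)) run_fit(config)
    est <- read.delim(est_path, comment.char = "#")
    r <- est$residual[est$cell_type == ct &
                        est$treatment == trt_labels[1L]] / 100
    if (!length(r)) stop_bad("no residual estimate for cell type '", ct, "'")
  }
  cmp <- compare_modes(trt, control_model, r)
  hist_trt <- cell_histogram(trt)
  meta <- run_meta(config)
  paths <- list(report = file.path(config$out_dir, "mode_report.json"),
                histogram = file.path(config$out_dir, "histogram.tsv"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(meta = meta, cell_type = ct, r = r,
         control_fit = list(mu = control_model$mu,
                            theta = control_model$theta,
                            theta_at_bound = control_model$theta_at_bound),
         comparison = unclass(cmp),
         treated_median = hist_trt$median),
    paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(paths$histogram, "w"); write_meta_header(con, meta)
  write.table(hist_trt$histogram, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  invisible(paths)
}

#' @rdname run_simulate
#' @export
run_summarize <- function(config) {
  est_path <- file.path(config$out_dir, "estimates.tsv")
  if (!file.exists(est_path)) run_fit(config)
  est <- read.delim(est_path, comment.char = "#")
  if (!nrow(est) || all(is.na(est$residual)))
    stop_bad("no residual estimates to summarize")
  inp <- load_inputs(config)

  # overall residual from the all-cells aggregate (one pseudobulk row per
  # animal, cell types pooled), not the mean of per-type residuals
  ann_all <- inp$annotations
  ann_all$cell_type <- "all"
  pb_all <- aggregate_pseudobulk(inp$counts, ann_all, config$target_feature)
  fit_all <- fit_nb_offset_model(
    pb_all, design_spec(pb_all, config$reference_treatment))
  overall <- residual_fractions(fit_all)

  meta <- run_meta(config)
  treatments <- unique(est$treatment[!is.na(est$treatment)])
  profiles <- lapply(treatments, function(trt) {
    e <- est[est$treatment == trt, ]
    ov <- overall$residual[overall$treatment == trt] * 100
    pr <- difference_from_overall(e$cell_type, e$residual, ov,
                                  n_cells = e$n_cells, condition = trt)
    cbind(treatment = trt, as.data.frame(pr), overall = ov)
  })
  profile <- do.call(rbind, profiles)
  wsd <- vapply(treatments, function(trt) {
    e <- est[est$treatment == trt, ]
    if (nrow(e) < 2) return(NA_real_)
    weighted_sd(e$residual, e$n_cells)
  }, 0)

  # correlogram across treatment profiles (shared cell types, weights =
  # summed cell counts)
  cor_mat <- matrix(1, length(treatments), length(treatments),
                    dimnames = list(treatments, treatments))
  cor_rows <- list()
  if (length(treatments) >= 2) {
    for (i in seq_along(treatments)) for (j in seq_along(treatments)) {
      if (j <= i) next
      a <- est[est$treatment == treatments[i], ]
      b <- est[est$treatment == treatments[j], ]
      shared <- intersect(a$cell_type, b$cell_type)
      if (length(shared) < 3) next
      ia <- match(shared, a$cell_type); ib <- match(shared, b$cell_type)
      wp <- weighted_pearson(a$residual[ia], b$residual[ib],
                             a$n_cells[ia] + b$n_cells[ib])
      cor_mat[i, j] <- cor_mat[j, i] <- wp$rho
      cor_rows[[length(cor_rows) + 1L]] <-
        data.frame(a = treatments[i], b = treatments[j], rho = wp$rho,
                   p_value = wp$p_value, n = wp$n)
    }
  }

  paths <- list(profile = file.path(config$out_dir, "profile.tsv"),
                summary = file.path(config$out_dir, "summary.json"),
                correlations = file.path(config$out_dir, "correlations.tsv"))
  con <- file(paths$profile, "w"); write_meta_header(con, meta)
  write.table(profile, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(meta = meta,
         overall_residual_pct = setNames(
           as.list(overall$residual * 100), overall$treatment),
         weighted_sd_pct = setNames(as.list(wsd), treatments),
         correlations = cor_rows),
    paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(paths$correlations, "w"); write_meta_header(con, meta)
  write.table(as.data.frame(cor_mat), con, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  close(con)
  invisible(paths)
}

#' @rdname run_simulate
#' @export
run_all <- function(config) {
  paths <- list()
  if (!is.null(config$cohort)) paths <- c(paths, run_simulate(config))
  paths <- c(paths, run_aggregate(config), run_fit(config))
  if (config$run_modes) paths <- c(paths, run_modes(config))
  invisible(c(paths, run_summarize(config)))
}
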