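#' Describe one cell type for the synthetic cohort generator
#'
#' @param name cell-type label.
#' @param proportion fraction of cells belonging to this type (the
#'   proportions of all types in a cohort must sum to 1).
#' @param basal_rate expected target UMIs per total UMI in control cells
#'   (a per-UMI rate in (0, 1); e.g. a target averaging 0.85 UMIs in cells
#'   with 7650 total UMIs has rate ~1.1e-4).
#' @param theta negative binomial dispersion (NB2: variance mu + mu^2/theta).
#' @param residual residual-target fraction r in \[0, 1\] under treatment;
#'   1 means no knockdown.
#' @return a `cell_type_spec` list.
#' @export
cell_type_spec <- function(name, proportion, basal_rate, theta, residual = 1) {
  check_number(proportion, "proportion", 0, 1, strict_lower = TRUE)
  check_number(basal_rate, "basal_rate", 0, strict_lower = TRUE)
  if (basal_rate >= 1) stop_bad("basal_rate must be < 1 (a per-UMI rate)")
  check_number(theta, "theta", 0, strict_lower = TRUE)
  check_number(residual, "residual", 0, 1)
  structure(list(name = as.character(name), proportion = proportion,
                 basal_rate = basal_rate, theta = theta, residual = residual),
            class = "cell_type_spec")
}

default_cell_types <- function() {
  # low-expression target in a small brain-region cohort: rates around
  # 1e-4 per UMI (~0.85 target UMIs in a median cell), knockdown depth
  # differing by type as real ASO data show
  list(
    cell_type_spec("neuron",    0.60, 1.2e-4, theta = 2, residual = 0.30),
    cell_type_spec("astrocyte", 0.25, 1.0e-4, theta = 2, residual = 0.56),
    cell_type_spec("microglia", 0.15, 0.8e-4, theta = 2, residual = 0.75)
  )
}

#' Specify a synthetic single-nucleus knockdown cohort
#'
#' Collects everything [generate_cohort()] needs: the cell-type mix with
#' basal target rates, dispersions and true residual fractions, the cohort
#' design (animals per arm, cells per animal), the library-size
#' distribution, the animal-level random effect, and the single-cell
#' knockdown architecture.
#'
#' @param cell_types list of [cell_type_spec()] objects; proportions must
#'   sum to 1.
#' @param n_animals_per_arm animals in each of the control and treated arms.
#' @param cells_per_animal nuclei sequenced per animal.
#' @param total_umi_logmean,total_umi_logsd log-normal parameters of the
#'   per-cell total-UMI (library size) distribution; defaults centre the
#'   distribution near 7650 UMIs per cell with realistic heavy tails.
#' @param animal_sigma SD of a per-animal log-scale random effect applied to
#'   the target mean only (biological replicate variability; default 0.05,
#'   about a 5% CV between animals).
#' @param knockdown_mode `"scaled_mu"` (every treated cell's mean is
#'   multiplied by its type's residual r) or `"zero_subset"` (a fraction
#'   1 - r of treated cells is silenced completely, the rest unchanged).
#' @param target_name feature id given to the target gene.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(cell_types = default_cell_types(),
                        n_animals_per_arm = 4,
                        cells_per_animal = 2000,
                        total_umi_logmean = log(7650),
                        total_umi_logsd = 0.5,
                        animal_sigma = 0.05,
                        knockdown_mode = c("scaled_mu", "zero_subset"),
                        target_name = "TARGET",
                        seed = 1L) {
  if (!length(cell_types) || !all(vapply(cell_types, inherits, TRUE,
                                         "cell_type_spec")))
    stop_bad("cell_types must be a non-empty list of cell_type_spec objects")
  props <- vapply(cell_types, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop_bad("cell-type proportions must sum to 1 (got ", sum(props), ")")
  nms <- vapply(cell_types, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_bad("duplicate cell-type names")
  check_count(n_animals_per_arm, "n_animals_per_arm")
  check_count(cells_per_animal, "cells_per_animal")
  check_number(total_umi_logsd, "total_umi_logsd", 0)
  check_number(animal_sigma, "animal_sigma", 0)
  knockdown_mode <- match.arg(knockdown_mode)
  structure(list(cell_types = cell_types,
                 n_animals_per_arm = as.integer(n_animals_per_arm),
                 cells_per_animal = as.integer(cells_per_animal),
                 total_umi_logmean = total_umi_logmean,
                 total_umi_logsd = total_umi_logsd,
                 animal_sigma = animal_sigma,
                 knockdown_mode = knockdown_mode,
                 target_name = target_name,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Generate a synthetic single-nucleus knockdown cohort
#'
#' Simulates the count structure the pseudobulk knockdown model assumes.
#' Each cell draws a total-UMI library size (log-normal, rounded, floor
#' 100). Control cells draw target counts from
#' NB2(mean = basal_rate x total x exp(animal effect), dispersion theta).
#' Treated cells follow `spec$knockdown_mode`: under `scaled_mu` the
#' NB mean is multiplied by the type's residual r (uniform partial
#' knockdown in every cell); under `zero_subset` each cell keeps the control
#' distribution with probability r and is set to zero otherwise (complete
#' silencing of a 1 - r subset). Both modes have treated/control mean ratio
#' exactly r, so they are indistinguishable in pseudobulk and differ only
#' in the per-cell count distribution -- the contrast [compare_modes()]
#' exploits. A single aggregate "other" feature row absorbs the remaining
#' UMIs so every column sums exactly to its drawn total (target counts are
#' capped at the cell's total, which at realistic basal rates is never
#' binding).
#'
#' @param spec a [cohort_spec()].
#' @return a `synthetic_cohort` list: `counts` (sparse 2 x cells matrix:
#'   target row + "other" row), `annotations` (one row per barcode), and
#'   `truth` (the generating spec).
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 7, cells_per_animal = 200))
#' table(co$annotations$treatment, co$annotations$cell_type)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_bad("spec must be a cohort_spec")
  with_seed(spec$seed, {
    n_arm <- spec$n_animals_per_arm
    animals <- c(sprintf("CTL%02d", seq_len(n_arm)),
                 sprintf("ASO%02d", seq_len(n_arm)))
    arms <- rep(c("control", "ASO"), each = n_arm)
    a_eff <- rnorm(2L * n_arm, 0, spec$animal_sigma)

    nms    <- vapply(spec$cell_types, `[[`, "", "name")
    props  <- vapply(spec$cell_types, `[[`, 0, "proportion")
    rates  <- vapply(spec$cell_types, `[[`, 0, "basal_rate")
    thetas <- vapply(spec$cell_types, `[[`, 0, "theta")
    resid  <- vapply(spec$cell_types, `[[`, 0, "residual")

    per_animal <- lapply(seq_along(animals), function(j) {
      n <- spec$cells_per_animal
      ct <- sample(seq_along(nms), n, replace = TRUE, prob = props)
      totals <- pmax(100, round(rlnorm(n, spec$total_umi_logmean,
                                       spec$total_umi_logsd)))
      mu <- rates[ct] * totals * exp(a_eff[j])
      treated <- arms[j] != "control"
      if (treated && spec$knockdown_mode == "scaled_mu") mu <- mu * resid[ct]
      y <- rnbinom(n, size = thetas[ct], mu = mu)
      if (treated && spec$knockdown_mode == "zero_subset")
        y <- y * rbinom(n, 1L, resid[ct])
      y <- pmin(y, totals)
      data.frame(barcode = sprintf("%s_c%05d", animals[j], seq_len(n)),
                 animal = animals[j], treatment = arms[j],
                 cell_type = nms[ct], region = "synthetic",
                 weeks_post_dose = 12,
                 target = y, total = totals, stringsAsFactors = FALSE)
    })
    cells <- do.call(rbind, per_animal)

    counts <- Matrix::sparseMatrix(
      i = rep(1:2, each = nrow(cells)),
      j = rep(seq_len(nrow(cells)), 2L),
      x = c(cells$target, cells$total - cells$target),
      dims = c(2L, nrow(cells)),
      dimnames = list(c(spec$target_name, "other"), cells$barcode))
    counts <- as(counts, "CsparseMatrix")

    ann <- cells[, c("barcode", "animal", "treatment", "cell_type",
                     "region", "weeks_post_dose")]
    rownames(ann) <- NULL
    structure(list(counts = counts, annotations = ann, truth = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", ncol(x$counts), "cells,",
      length(x$truth$cell_types), "cell types,",
      x$truth$n_animals_per_arm, "+", x$truth$n_animals_per_arm, "animals,",
      "mode", x$truth$knockdown_mode, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the 10x-style triplet layout ([write_counts()]), the annotation
#' TSV and the generating spec as YAML under `dir_path`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir_path output directory.
#' @return invisibly, named list of paths.
#' @export
write_cohort <- function(cohort, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  paths <- write_counts(cohort$counts, dir_path)
  paths$annotations <- file.path(dir_path, "annotations.tsv")
  write_annotations(cohort$annotations, paths$annotations)
  paths$truth <- file.path(dir_path, "truth.yaml")
  truth <- cohort$truth
  truth$cell_types <- lapply(truth$cell_types, unclass)
  yaml::write_yaml(unclass(truth), paths$truth)
  invisible(paths)
}

#' Generate a synthetic qPCR Ct table with known residual
#'
#' Builds target and housekeeping Ct values for a control and a treated arm
#' such that, at zero noise, the delta-delta-Ct residual
#' ([ddct_residual()]) equals `residual_truth` exactly: treated samples'
#' delta-Ct exceeds the control mean delta-Ct by -log2(residual_truth)
#' cycles. Gaussian noise of SD `ct_noise_sd` is added to every Ct
#' measurement independently.
#'
#' @param residual_truth true residual fraction in (0, 1].
#' @param n_per_arm biological samples per arm.
#' @param ct_noise_sd measurement noise SD in Ct units.
#' @param seed integer seed.
#' @param n_replicates technical replicates per sample (averaged on the Ct
#'   scale by [ddct_residual()]).
#' @return data.frame with columns `sample`, `treatment`, `ct_target`,
#'   `ct_housekeeping`.
#' @export
generate_qpcr_table <- function(residual_truth, n_per_arm = 4,
                                ct_noise_sd = 0, seed = 1L,
                                n_replicates = 1L) {
  check_number(residual_truth, "residual_truth", 0, 1, strict_lower = TRUE)
  check_count(n_per_arm, "n_per_arm")
  check_number(ct_noise_sd, "ct_noise_sd", 0)
  check_count(n_replicates, "n_replicates")
  ct_hk <- 20; dct_control <- 5  # typical housekeeping / target Ct levels
  with_seed(seed, {
    arm <- rep(c("control", "ASO"), each = n_per_arm)
    samp <- c(sprintf("CTL%02d", seq_len(n_per_arm)),
              sprintf("ASO%02d", seq_len(n_per_arm)))
    dct <- ifelse(arm == "control", dct_control,
                  dct_control - log2(residual_truth))
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(sample = samp, treatment = arm,
                 ct_target = ct_hk + dct +
                   rnorm(length(samp), 0, ct_noise_sd),
                 ct_housekeeping = ct_hk +
                   rnorm(length(samp), 0, ct_noise_sd),
                 stringsAsFactors = FALSE)
    }))
    out[order(out$sample), ]
  })
}
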