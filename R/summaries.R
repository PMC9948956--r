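#' Frequency-weighted Pearson correlation
#'
#' Pearson correlation in which each observation (here, a cell type)
#' carries a frequency weight, typically its number of sequenced cells, so
#' abundant cell types with tight confidence intervals dominate rare ones.
#' Weights are normalized to sum to n before computing weighted means,
#' variances and covariance; the p-value uses the t statistic
#' `rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom,
#' two-sided.
#'
#' @param x,y numeric vectors (e.g. residual percentages per cell type).
#' @param w positive weights, one per observation (default equal, which
#'   reduces exactly to the ordinary Pearson correlation).
#' @return list with `rho`, `p_value`, `n`.
#' @examples
#' weighted_pearson(c(1, 2, 3), c(2, 5, 8))            # rho = 1
#' weighted_pearson(c(30, 56, 75), c(28, 60, 70), w = c(1200, 500, 300))
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (n < 3L) stop_bad("need at least 3 observations")
  if (length(y) != n || length(w) != n)
    stop_bad("x, y and w must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_bad("x and y must be finite")
  if (any(w <= 0)) stop_bad("weights must be positive")
  w <- w / sum(w) * n
  xb <- sum(w * x) / n
  yb <- sum(w * y) / n
  vx <- sum(w * (x - xb)^2) / (n - 1)
  vy <- sum(w * (y - yb)^2) / (n - 1)
  if (vx == 0 || vy == 0) stop_bad("zero weighted variance in x or y")
  cxy <- sum(w * (x - xb) * (y - yb)) / (n - 1)
  rho <- max(-1, min(1, cxy / sqrt(vx * vy)))
  p <- if (abs(rho) == 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Frequency-weighted standard deviation
#'
#' Square root of the frequency-weighted unbiased variance with weights
#' normalized to sum to n. With equal weights this is the ordinary sample
#' SD. Used to quantify the spread of residual-target percentages across
#' cell types, weighting by number of cells.
#'
#' @inheritParams weighted_pearson
#' @param values numeric vector.
#' @return a single number.
#' @export
weighted_sd <- function(values, w = rep(1, length(values))) {
  n <- length(values)
  if (n < 2L) stop_bad("need at least 2 values")
  if (length(w) != n) stop_bad("values and w must have equal length")
  if (any(w <= 0)) stop_bad("weights must be positive")
  w <- w / sum(w) * n
  m <- sum(w * values) / n
  sqrt(sum(w * (values - m)^2) / (n - 1))
}

#' Difference-from-overall-residual profile for one condition
#'
#' Normalizes cell-type knockdown profiles between conditions with
#' different overall potency: each cell type's residual target (percent of
#' control) minus the overall residual across all cells of the condition.
#' Positive differences mean the cell type has weaker knockdown than the
#' bulk tissue; negative, deeper. The overall residual should come from the
#' all-cells pseudobulk aggregate of the condition, not from averaging the
#' per-type residuals.
#'
#' Both inputs must be on the percent (0-100) scale; a mixture of fractions
#' and percents is rejected.
#'
#' @param cell_types cell-type labels.
#' @param residual_pct per-cell-type residual target, percent of control.
#' @param overall_pct overall residual of the condition, percent.
#' @param n_cells optional cells per type (carried for weighting).
#' @param condition optional condition label (region / ASO / timepoint).
#' @return a `condition_profile` data.frame: `cell_type`, `residual`,
#'   `difference`, `n_cells`, with attributes `overall` and `condition`.
#' @export
difference_from_overall <- function(cell_types, residual_pct, overall_pct,
                                    n_cells = NULL, condition = "") {
  if (length(residual_pct) != length(cell_types))
    stop_bad("cell_types and residual_pct must have equal length")
  check_number(overall_pct, "overall_pct", 0)
  looks_frac <- function(v) all(v >= 0 & v <= 1.5)
  if (looks_frac(residual_pct) != looks_frac(overall_pct))
    stop_bad("residual_pct and overall_pct appear to be on different ",
             "scales (fractions mixed with percents)")
  if (looks_frac(residual_pct) && looks_frac(overall_pct))
    stop_bad("inputs look like fractions; supply percents (0-100)")
  out <- data.frame(cell_type = cell_types,
                    residual = residual_pct,
                    difference = residual_pct - overall_pct,
                    n_cells = if (is.null(n_cells)) NA_integer_
                              else as.integer(n_cells),
                    stringsAsFactors = FALSE)
  attr(out, "overall") <- overall_pct
  attr(out, "condition") <- condition
  class(out) <- c("condition_profile", "data.frame")
  out
}

#' Washout recovery between two timepoints
#'
#' The rise in residual target between an early and a late post-dose
#' timepoint, in percentage points: `late - early`. A compound whose
#' residual target climbs from 47% to 91% of control has recovered 44
#' points.
#'
#' @param residual_early,residual_late residual target in percent.
#' @return percentage points of recovery (negative if knockdown deepened).
#' @export
recovery <- function(residual_early, residual_late) {
  residual_late - residual_early
}

#' Delta-delta-Ct residual expression from qPCR Ct values
#'
#' Classic relative quantification: technical replicates are averaged on
#' the Ct scale per sample; `delta Ct = ct_target - ct_housekeeping`
#' normalizes to the housekeeping gene; `delta delta Ct` subtracts the
#' reference (control) arm's mean delta Ct; residual expression is
#' `2^(-delta delta Ct) x 100%`. Per-arm summaries are computed on the Ct
#' scale then transformed (a geometric mean), so the reference arm summary
#' is exactly 100% by construction.
#'
#' @param q data.frame with columns `sample`, `treatment`, `ct_target`,
#'   `ct_housekeeping` (one row per technical replicate).
#' @param reference_treatment label of the control arm.
#' @return list with `per_sample` (columns `sample`, `treatment`,
#'   `delta_ct`, `delta_delta_ct`, `residual_pct`) and `per_arm`
#'   (`treatment`, `residual_pct`).
#' @export
ddct_residual <- function(q, reference_treatment = "control") {
  need <- c("sample", "treatment", "ct_target", "ct_housekeeping")
  miss <- setdiff(need, names(q))
  if (length(miss))
    stop_bad("qPCR table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(q$ct_target)) || any(!is.finite(q$ct_housekeeping)))
    stop_bad("Ct values must be finite")
  if (!reference_treatment %in% q$treatment)
    stop_bad("no sample with reference treatment '", reference_treatment, "'")
  agg <- aggregate(q[c("ct_target", "ct_housekeeping")],
                   by = q[c("sample", "treatment")], FUN = mean)
  agg$delta_ct <- agg$ct_target - agg$ct_housekeeping
  ref_mean <- mean(agg$delta_ct[agg$treatment == reference_treatment])
  agg$delta_delta_ct <- agg$delta_ct - ref_mean
  agg$residual_pct <- 2^(-agg$delta_delta_ct) * 100
  per_sample <- agg[order(agg$treatment != reference_treatment, agg$sample),
                    c("sample", "treatment", "delta_ct", "delta_delta_ct",
                      "residual_pct")]
  rownames(per_sample) <- NULL
  arm_ddct <- tapply(agg$delta_delta_ct, agg$treatment, mean)
  per_arm <- data.frame(treatment = names(arm_ddct),
                        residual_pct = 2^(-as.numeric(arm_ddct)) * 100,
                        stringsAsFactors = FALSE)
  rownames(per_arm) <- NULL
  list(per_sample = per_sample, per_arm = per_arm)
}

#' How many drug molecules does a dose put in each cell?
#'
#' Converts an ASO dose to molecule counts: total molecules = dose mass /
#' molecular weight x Avogadro's number; divided by the number of cells in
#' the tissue; optionally scaled by the fraction of molecules undergoing
#' productive uptake. A 50 ug dose of a ~7 kDa ASO is ~4e15 molecules --
#' more than 1e7 per cell in a ~1e8-cell mouse brain, and still 1e5 per
#' cell if only 1% of uptake is productive, which is why no cell is likely
#' to escape exposure by chance.
#'
#' @param dose_mass dose in grams (50 ug = `50e-6`).
#' @param molecular_weight g/mol (7 kDa = `7000`).
#' @param n_cells number of cells in the dosed tissue.
#' @param productive_fraction fraction of molecules productively taken up,
#'   in \[0, 1\].
#' @return list with `total_molecules`, `per_cell`, `productive_per_cell`.
#' @examples
#' molecules_per_cell(50e-6, 7000, 1e8, productive_fraction = 0.01)
#' @export
molecules_per_cell <- function(dose_mass, molecular_weight, n_cells,
                               productive_fraction = 1) {
  check_number(dose_mass, "dose_mass", 0, strict_lower = TRUE)
  check_number(molecular_weight, "molecular_weight", 0, strict_lower = TRUE)
  check_number(n_cells, "n_cells", 0, strict_lower = TRUE)
  check_number(productive_fraction, "productive_fraction", 0, 1)
  avogadro <- 6.02214076e23
  total <- dose_mass / molecular_weight * avogadro
  per_cell <- total / n_cells
  list(total_molecules = total, per_cell = per_cell,
       productive_per_cell = per_cell * productive_fraction)
}
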