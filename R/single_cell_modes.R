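#' Fit a marginal negative binomial to control-cell target counts
#'
#' Maximum-likelihood NB2 fit of a single (mu, theta) to the pooled
#' per-cell target counts of control cells -- the null model the observed
#' count histogram is compared against. Counts are modeled marginally (one
#' mu for all cells, matching a single fitted curve over the pooled
#' histogram); set `per_10k = TRUE` to first rescale each cell's count to a
#' common exposure of 10,000 total UMIs as a sensitivity variant.
#'
#' Near-Poisson data drive theta upward without bound; the search caps
#' `log(theta)` at 15 and flags the fit `theta_at_bound`.
#'
#' @param cells integer vector of per-cell target counts, or a data.frame
#'   with columns `target_umi` (and `total_umi`, required if
#'   `per_10k = TRUE`) as returned by [per_cell_target_counts()].
#' @param per_10k rescale counts to a common 10k-UMI exposure first.
#' @param min_cells minimum number of cells (default 30).
#' @return a `histogram_model` list: `mode = "control_nb"`, `mu`, `theta`,
#'   `r = 1`, `loglik`, `converged`, `theta_at_bound`, `n`.
#' @export
fit_control_nb <- function(cells, per_10k = FALSE, min_cells = 30L) {
  y <- cells_to_counts(cells, per_10k)
  if (length(y) < min_cells)
    stop_bad("need at least ", min_cells, " cells (got ", length(y), ")")
  if (all(y == 0)) stop_bad("all target counts are zero; nothing to fit")
  negll <- function(par) -sum(nb2_logpmf(y, exp(par[1L]), exp(par[2L])))
  start <- c(log(mean(y)),
             log(max(1e-3, min(3e6, mean(y)^2 /
                                 max(var(y) - mean(y), 1e-8)))))
  opt <- optim(start, negll, method = "L-BFGS-B",
               lower = c(-20, -10), upper = c(20, 15))
  # Poisson-like data leave the theta profile flat up to the cap; flag the
  # fit when the capped dispersion is not distinguishable from infinite
  # theta by a profile LRT (boundary-corrected 95% cutoff, 0.5*chisq(1))
  at_bound <- opt$par[2L] >= 15 - 1e-6 ||
    (-negll(c(opt$par[1L], 15))) >= (-opt$value) - qchisq(0.90, 1) / 2
  structure(list(mode = "control_nb",
                 mu = exp(opt$par[1L]), theta = exp(opt$par[2L]), r = 1,
                 loglik = -opt$value,
                 converged = opt$convergence == 0L,
                 theta_at_bound = at_bound,
                 n = length(y)),
            class = "histogram_model")
}

cells_to_counts <- function(cells, per_10k = FALSE) {
  if (is.data.frame(cells)) {
    if (!"target_umi" %in% names(cells))
      stop_bad("cells data.frame needs a target_umi column")
    y <- cells$target_umi
    if (per_10k) {
      if (!"total_umi" %in% names(cells))
        stop_bad("per_10k = TRUE needs a total_umi column")
      y <- round(y / cells$total_umi * 1e4)
    }
  } else {
    if (per_10k) stop_bad("per_10k = TRUE needs a data.frame with totals")
    y <- cells
  }
  if (any(y < 0)) stop_bad("negative target count")
  as.numeric(y)
}

#' @export
print.histogram_model <- function(x, ...) {
  cat("histogram_model [", x$mode, "]: mu =", signif(x$mu, 4),
      ", theta =", signif(x$theta, 4), ", r =", signif(x$r, 4), "\n")
  invisible(x)
}

# shared PMF engine over counts 0..K plus a lumped tail
candidate_pmf <- function(mu, theta, r, mode, max_count) {
  k <- 0:max_count
  if (mode == "scaled_mu") {
    p <- dnbinom(k, size = theta, mu = r * mu)
  } else {
    p <- r * dnbinom(k, size = theta, mu = mu) + (1 - r) * (k == 0)
  }
  structure(p, names = as.character(k), tail = max(0, 1 - sum(p)),
            mode = mode, mu = mu, theta = theta, r = r)
}

default_support <- function(model) max(1L, qnbinom(0.999, size = model$theta,
                                                  mu = model$mu))

#' Candidate PMFs for the two single-cell knockdown architectures
#'
#' Given the control-cell NB fit and a bulk residual fraction r, the two
#' hypotheses about how knockdown is distributed over cells are:
#'
#' * **scaled-mu** -- equal partial knockdown in every cell: the NB mean is
#'   reduced to `r * mu` at unchanged theta, so
#'   `P(0) = (theta / (theta + r * mu))^theta`;
#' * **zero-subset** -- complete silencing of a `1 - r` subset: the mixture
#'   `r * NB(mu, theta) + (1 - r) * delta_0`, so
#'   `P(0) = (1 - r) + r * (theta / (theta + mu))^theta`.
#'
#' Both have mean exactly `r * mu`; they differ in zero mass (the
#' zero-subset PMF always has at least as many zeros) and higher moments,
#' which is what makes them distinguishable from a histogram.
#'
#' @param model a `histogram_model` from [fit_control_nb()].
#' @param r residual fraction (scaled-mu requires r > 0; zero-subset
#'   admits r = 0, a point mass at zero).
#' @param max_count truncate the support at this count; probabilities
#'   beyond it are lumped into a `tail` attribute. Defaults to the 99.9th
#'   percentile of the control fit.
#' @return named numeric vector of probabilities for counts `0..max_count`
#'   with attributes `tail`, `mode`, `mu`, `theta`, `r`.
#' @export
pmf_scaled_mu <- function(model, r, max_count = default_support(model)) {
  check_number(r, "r", 0, 1, strict_lower = TRUE)
  candidate_pmf(model$mu, model$theta, r, "scaled_mu", max_count)
}

#' @rdname pmf_scaled_mu
#' @export
pmf_zero_subset <- function(model, r, max_count = default_support(model)) {
  check_number(r, "r", 0, 1)
  candidate_pmf(model$mu, model$theta, r, "zero_subset", max_count)
}

#' Which single-cell knockdown architecture explains treated counts?
#'
#' Bins the observed treated-cell counts (support truncated at the smaller
#' of the observed maximum and the 99.9th percentile of the control fit,
#' remainder in a tail bin) and scores the histogram under the two
#' candidate PMFs of [pmf_scaled_mu()]/[pmf_zero_subset()] by multinomial
#' log-likelihood. The preferred architecture is the higher-likelihood one;
#' the call is `"indeterminate"` when `|delta log-likelihood| < 2`
#' (conventional likelihood-comparison slack -- at r = 1 the two models
#' coincide and no data can separate them). Total-variation distances of
#' each candidate to the observed histogram are reported alongside.
#'
#' @param treated_cells integer vector of per-cell target counts in the
#'   treated arm (or data.frame with `target_umi`), at least 30 cells.
#' @param control_model `histogram_model` fitted to control cells.
#' @param r residual fraction, typically the pseudobulk estimate from
#'   [residual_fractions()].
#' @return a `mode_comparison` list: `loglik_scaled`, `loglik_subset`,
#'   `delta` (scaled minus subset), `preferred`, `tv_scaled`, `tv_subset`,
#'   `p0_scaled`, `p0_subset`, `observed_zero_fraction`, `n`.
#' @export
compare_modes <- function(treated_cells, control_model, r) {
  y <- cells_to_counts(treated_cells)
  if (!length(y)) stop_bad("no treated cells supplied")
  if (length(y) < 30L)
    stop_bad("need at least 30 treated cells (got ", length(y), ")")
  check_number(r, "r", 0, 1, strict_lower = TRUE)
  K <- min(max(y), default_support(control_model))
  p_scaled <- pmf_scaled_mu(control_model, r, max_count = K)
  p_subset <- pmf_zero_subset(control_model, r, max_count = K)
  obs <- tabulate(pmin(y, K + 1) + 1L, nbins = K + 2L)  # last bin = tail
  mult_ll <- function(p) {
    probs <- pmax(c(as.numeric(p), attr(p, "tail")), 1e-12)
    sum(obs * log(probs))
  }
  ll_s <- mult_ll(p_scaled); ll_z <- mult_ll(p_subset)
  delta <- ll_s - ll_z
  preferred <- if (abs(delta) < 2) "indeterminate"
               else if (delta > 0) "scaled_mu" else "zero_subset"
  freq <- obs / sum(obs)
  tv <- function(p) 0.5 * sum(abs(freq - c(as.numeric(p), attr(p, "tail"))))
  structure(list(loglik_scaled = ll_s, loglik_subset = ll_z, delta = delta,
                 preferred = preferred,
                 tv_scaled = tv(p_scaled), tv_subset = tv(p_subset),
                 p0_scaled = unname(p_scaled[1L]),
                 p0_subset = unname(p_subset[1L]),
                 observed_zero_fraction = mean(y == 0), n = length(y)),
            class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("mode comparison over", x$n, "cells: preferred =", x$preferred,
      sprintf("(delta loglik = %.2f)\n", x$delta))
  cat(sprintf("  P(0): scaled_mu %.4f, zero_subset %.4f, observed %.4f\n",
              x$p0_scaled, x$p0_subset, x$observed_zero_fraction))
  invisible(x)
}

#' Histogram of per-cell target counts
#'
#' Integer-binned histogram of target UMIs per cell, plus the median count
#' (the field's usual summary of such histograms).
#'
#' @param cells integer vector of counts or data.frame with `target_umi`.
#' @param bin_width bin width in UMIs (default 1; wider bins suit abundant
#'   targets with counts in the hundreds).
#' @return list with `histogram` (data.frame `bin_start`, `n`) and
#'   `median`.
#' @export
cell_histogram <- function(cells, bin_width = 1) {
  y <- cells_to_counts(cells)
  if (!length(y)) stop_bad("no cells supplied")
  check_number(bin_width, "bin_width", 0, strict_lower = TRUE)
  bin <- floor(y / bin_width) * bin_width
  tab <- table(bin)
  list(histogram = data.frame(bin_start = as.numeric(names(tab)),
                              n = as.integer(tab)),
       median = median(y))
}
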