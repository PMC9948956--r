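# fixtures and independent oracles shared across test files

# tiny hand-built count matrix: 3 features x 4 cells, two animals
toy_matrix <- function() {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3, 3, 1),
    j = c(1, 2, 2, 3, 4, 4),
    x = c(3, 5, 2, 7, 4, 1),
    dims = c(3, 4),
    dimnames = list(c("TARGET", "geneB", "geneC"),
                    c("bc1", "bc2", "bc3", "bc4")))
  as(m, "CsparseMatrix")
}

toy_annotations <- function() {
  data.frame(barcode = c("bc1", "bc2", "bc3", "bc4"),
             animal = c("A1", "A1", "A2", "A2"),
             treatment = c("control", "control", "ASO", "ASO"),
             cell_type = c("neuron", "neuron", "neuron", "glia"),
             region = "ctx", weeks_post_dose = 2,
             stringsAsFactors = FALSE)
}

# small pseudobulk table with equal offsets (closed-form MLE available)
equal_offset_table <- function(counts_ctl = c(80, 120, 100, 100),
                               counts_trt = NULL, total = 10000) {
  n <- length(counts_ctl)
  tab <- data.frame(animal = sprintf("C%d", seq_len(n)), cell_type = "ct1",
                    treatment = "control", target_umi = counts_ctl,
                    total_umi = total, n_cells = 10L,
                    stringsAsFactors = FALSE)
  if (!is.null(counts_trt)) {
    tab <- rbind(tab, data.frame(
      animal = sprintf("T%d", seq_along(counts_trt)), cell_type = "ct1",
      treatment = "ASO", target_umi = counts_trt, total_umi = total,
      n_cells = 10L, stringsAsFactors = FALSE))
  }
  tab
}

# independent NB2 log-likelihood oracle: dnbinom term by term
loglik_oracle <- function(table, beta, theta, design) {
  cts <- design$cell_types
  trts <- setdiff(design$treatments, design$reference_treatment)
  nm <- c(paste0("ct:", cts),
          as.vector(outer(cts, trts, function(a, b)
            paste0("ct:", a, ":trt:", b))))
  names(beta) <- nm
  ll <- 0
  for (i in seq_len(nrow(table))) {
    eta <- beta[paste0("ct:", table$cell_type[i])]
    if (table$treatment[i] != design$reference_treatment)
      eta <- eta + beta[paste0("ct:", table$cell_type[i], ":trt:",
                               table$treatment[i])]
    mu <- exp(eta) * table$total_umi[i]
    ll <- ll + dnbinom(table$target_umi[i], size = theta, mu = mu,
                       log = TRUE)
  }
  unname(ll)
}

# brute-force ML fit: Nelder-Mead over (beta, log theta) on nb_loglik,
# data-driven start (group log ratios) plus blind restarts, each polished
# by a Nelder-Mead restart from its own optimum
brute_force_fit <- function(table, design) {
  nm <- nb_coef_names(design)
  p <- length(nm)
  obj <- function(par) -nb_loglik(table, par[seq_len(p)],
                                  exp(par[p + 1L]), design)
  ratio_start <- vapply(nm, function(cn) {
    if (grepl(":trt:", cn)) {
      ct <- sub("^ct:(.*):trt:.*$", "\\1", cn)
      trt <- sub("^.*:trt:", "", cn)
      rows <- table$cell_type == ct & table$treatment == trt
      ref <- table$cell_type == ct &
        table$treatment == design$reference_treatment
      log((sum(table$target_umi[rows]) + 0.5) /
            sum(table$total_umi[rows])) -
        log((sum(table$target_umi[ref]) + 0.5) / sum(table$total_umi[ref]))
    } else {
      ct <- sub("^ct:", "", cn)
      ref <- table$cell_type == ct &
        table$treatment == design$reference_treatment
      log((sum(table$target_umi[ref]) + 0.5) / sum(table$total_umi[ref]))
    }
  }, 0)
  best <- NULL
  for (s in list(c(ratio_start, 0), c(ratio_start, 4),
                 c(rep(-5, p), 0))) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
    for (k in 1:3)  # restarting Nelder-Mead re-expands the simplex
      o <- optim(o$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(beta = unname(best$par[seq_len(p)]), theta = exp(best$par[p + 1L]),
       loglik = -best$value)
}

# one-cell-type cohort spec used by ratio / recovery simulations
single_type_spec <- function(r, seed, p = 0.01, theta = 2,
                             cells = 2000, mode = "scaled_mu") {
  cohort_spec(cell_types = list(cell_type_spec("ct1", 1, p, theta = theta,
                                               residual = r)),
              cells_per_animal = cells, animal_sigma = 0,
              knockdown_mode = mode, seed = seed)
}

# generator defaults with the three benchmark residuals, for coverage runs
coverage_spec <- function(seed) {
  cohort_spec(cell_types = list(
    cell_type_spec("neuron",    0.60, 1.2e-4, theta = 2, residual = 0.1),
    cell_type_spec("astrocyte", 0.25, 1.0e-4, theta = 2, residual = 0.5),
    cell_type_spec("microglia", 0.15, 0.8e-4, theta = 2, residual = 0.9)),
    cells_per_animal = 2000, animal_sigma = 0, seed = seed)
}

coverage_truth <- c(neuron = 0.1, astrocyte = 0.5, microglia = 0.9)
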