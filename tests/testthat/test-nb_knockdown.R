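test_that("nb_loglik matches closed forms and the dnbinom oracle", {
  tab1 <- data.frame(animal = "a", cell_type = "ct1", treatment = "control",
                     target_umi = 0L, total_umi = 1L, n_cells = 1L)
  des1 <- design_spec(tab1)
  # y = 0, mu = 1, theta = 1: P = (theta/(theta+mu))^theta = 1/2
  expect_equal(nb_loglik(tab1, beta = 0, theta = 1, des1), log(0.5),
               tolerance = 1e-12)
  # theta -> Inf approaches the Poisson log-likelihood
  tab2 <- tab1; tab2$target_umi <- 7L; tab2$total_umi <- 10L
  expect_equal(nb_loglik(tab2, beta = 0, theta = 1e8, des1),
               dpois(7, 10, log = TRUE), tolerance = 1e-4)

  # random small table against a term-by-term dnbinom oracle
  set.seed(31)
  tab <- data.frame(
    animal = rep(sprintf("a%d", 1:4), 2),
    cell_type = rep(c("ct1", "ct2"), each = 4),
    treatment = rep(c("control", "ASO"), 4),
    target_umi = rpois(8, 50),
    total_umi = sample(5000:20000, 8),
    n_cells = 10L)
  des <- design_spec(tab)
  for (i in 1:5) {
    beta <- rnorm(length(nb_coef_names(des)), -5, 1)
    theta <- exp(rnorm(1))
    expect_equal(nb_loglik(tab, beta, theta, des),
                 loglik_oracle(tab, beta, theta, des), tolerance = 1e-10)
  }
  expect_error(nb_loglik(tab, rep(NaN, 4), 1, des), "nonfinite")
  expect_error(nb_loglik(tab, rep(0, 4), -1, des), "theta")
})

test_that("equal-offset fits return exact ratio-of-sums estimates", {
  # intercept only: exp(beta0) equals the mean target fraction exactly
  tab <- equal_offset_table()
  fit <- fit_nb_offset_model(tab, design_spec(tab))
  expect_equal(unname(exp(fit$beta["ct:ct1"])), 0.01, tolerance = 1e-10)

  # symmetric treated arm: interaction is exactly log(0.5)
  tab2 <- equal_offset_table(counts_trt = c(40, 60, 50, 50))
  fit2 <- fit_nb_offset_model(tab2)
  expect_equal(unname(exp(fit2$beta["ct:ct1:trt:ASO"])), 0.5,
               tolerance = 1e-10)
})

test_that("fitter attains the brute-force likelihood optimum", {
  set.seed(11)
  tab <- data.frame(
    animal = rep(sprintf("a%d", 1:8), times = 3),
    cell_type = rep(c("ct1", "ct2", "ct3"), each = 8),
    treatment = rep(rep(c("control", "ASO"), each = 4), 3),
    target_umi = rnbinom(24, size = 5, mu = 60),
    total_umi = sample(8000:30000, 24),
    n_cells = 20L)
  des <- design_spec(tab)
  fit <- fit_nb_offset_model(tab, des)
  bf <- brute_force_fit(tab, des)
  expect_gte(fit$loglik, bf$loglik - 1e-6)
  expect_equal(unname(fit$beta), bf$beta, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("fit agrees with an independent GLM implementation", {
  co <- generate_cohort(cohort_spec(seed = 7, cells_per_animal = 500))
  pb <- aggregate_pseudobulk(co$counts, co$annotations, "TARGET")
  fit <- fit_nb_offset_model(pb)
  g <- suppressWarnings(MASS::glm.nb(
    target_umi ~ 0 + cell_type + cell_type:treatment +
      offset(log(total_umi)),
    data = transform(pb, treatment = factor(treatment,
                                            levels = c("ASO", "control")))))
  # interaction coefficients are shared between parameterizations (the
  # MASS contrast is control-relative-to-ASO, i.e. the negation)
  mine <- fit$beta[grep("trt:ASO", names(fit$beta))]
  theirs <- -coef(g)[grep("treatmentcontrol", names(coef(g)))]
  ord <- order(names(mine))
  expect_equal(unname(sort(mine)), unname(sort(theirs)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-3)
})

test_that("residual fractions exponentiate coefficients with log-scale CIs", {
  fake <- structure(list(
    beta = c("ct:ct1" = -5, "ct:ct1:trt:ASO" = log(0.5)),
    se = c("ct:ct1" = 0.05, "ct:ct1:trt:ASO" = 0.1),
    flags = c("ct:ct1" = "", "ct:ct1:trt:ASO" = ""),
    table = data.frame(cell_type = "ct1", n_cells = 100L),
    design = design_spec(cell_types = "ct1",
                         treatments = c("control", "ASO"))),
    class = "nb_fit")
  est <- residual_fractions(fake)
  expect_equal(est$residual, 0.5)
  expect_equal(est$ci_low, exp(log(0.5) - 0.196))
  expect_equal(est$ci_high, exp(log(0.5) + 0.196))
  expect_equal(round(est$ci_low * 100, 1), 41.1)
  expect_equal(round(est$ci_high * 100, 1), 60.8)

  # beta_int = 0: residual 100%, CI symmetric about 1 on the log scale
  fake$beta["ct:ct1:trt:ASO"] <- 0
  est0 <- residual_fractions(fake)
  expect_equal(est0$residual, 1)
  expect_equal(est0$ci_low * est0$ci_high, 1, tolerance = 1e-12)

  fake$design <- design_spec(cell_types = "ct1",
                             treatments = c("control", "ASO6"),
                             reference_treatment = "control")
  expect_error(residual_fractions(fake), "missing interaction")
})

test_that("per-animal estimates are exponentiated log-ratio residuals", {
  tab <- equal_offset_table(counts_trt = c(40, 60, 50, 50))
  fit <- fit_nb_offset_model(tab)
  pa <- per_animal_estimates(fit)
  # animal with y = mu_hat lands exactly on exp(beta_int)
  expect_equal(pa$residual[pa$animal == "T3"],
               unname(exp(fit$beta["ct:ct1:trt:ASO"])), tolerance = 1e-8)
  # log-ratio definition: estimate scales linearly in y
  expect_equal(pa$residual[pa$animal == "T2"] /
                 pa$residual[pa$animal == "T3"], 60 / 50,
               tolerance = 1e-8)
  # total-UMI-weighted mean reproduces the pooled observed ratio
  trt <- fit$table$treatment == "ASO"
  pooled <- (sum(fit$table$target_umi[trt]) /
               sum(fit$table$total_umi[trt])) /
    exp(unname(fit$beta["ct:ct1"]))
  expect_equal(sum(pa$residual * fit$table$total_umi[trt]) /
                 sum(fit$table$total_umi[trt]), pooled, tolerance = 1e-8)
})

test_that("all-zero treated groups are flagged, not dropped", {
  tab <- equal_offset_table(counts_trt = c(0, 0, 0, 0))
  fit <- expect_silent(fit_nb_offset_model(tab))
  est <- residual_fractions(fit)
  expect_equal(est$flag, "zero_counts")
  expect_true(is.finite(est$residual) && est$residual > 0)
  expect_true(all(per_animal_estimates(fit)$flag == "zero_corrected"))
})

test_that("cell-type order does not change the estimates", {
  co <- generate_cohort(cohort_spec(seed = 13, cells_per_animal = 300))
  pb <- aggregate_pseudobulk(co$counts, co$annotations, "TARGET")
  d1 <- design_spec(pb, cell_types = c("astrocyte", "microglia", "neuron"))
  d2 <- design_spec(pb, cell_types = c("neuron", "astrocyte", "microglia"))
  e1 <- residual_fractions(fit_nb_offset_model(pb, d1))
  e2 <- residual_fractions(fit_nb_offset_model(pb, d2))
  e2 <- e2[match(e1$cell_type, e2$cell_type), ]
  expect_equal(e1$residual, e2$residual, tolerance = 1e-8)
})

test_that("confidence intervals shrink with more cells", {
  width <- vapply(c(200, 800, 3200), function(n) {
    co <- generate_cohort(single_type_spec(r = 0.5, seed = 21, cells = n))
    pb <- aggregate_pseudobulk(co$counts, co$annotations, "TARGET")
    est <- residual_fractions(fit_nb_offset_model(pb))
    est$ci_high - est$ci_low
  }, 0)
  expect_true(width[1] > width[2] && width[2] > width[3])
})

test_that("fit preconditions are enforced", {
  tab <- equal_offset_table(counts_trt = c(40, 60, 50, 50))
  no_ref <- tab[tab$treatment != "control", ]
  expect_error(fit_nb_offset_model(no_ref), "no reference-arm row")
  bad <- tab; bad$total_umi[1] <- 0
  expect_error(fit_nb_offset_model(bad), "total_umi|target_umi")
})
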