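test_that("individual fits recover noise-free parameters and are order/duplication invariant", {
  pop <- table2_pop()
  reg <- study_regimen()
  local_seed(808)
  truth <- pk_params(cl = 22, vc = 15, vp = 30, q = 28, alag = 0.13)
  tt <- sampling_design("rich")
  rec <- data.frame(time_h = as.numeric(tt),
                    conc_obs_mg_L = conc_steady_state(truth, reg, as.numeric(tt)),
                    blq = FALSE)
  rec <- rec[rec$time_h > 0 | rec$conc_obs_mg_L > 0, ]
  init <- pk_params(16.3, 19.9, 18.8, 37.3, alag = 0.13)
  f <- fit_individual(rec, reg, init, pop)
  expect_true(f$converged)
  expect_equal(f$pars$cl, truth$cl, tolerance = 1e-3)
  expect_equal(f$pars$vc, truth$vc, tolerance = 1e-3)
  expect_equal(f$pars$vp, truth$vp, tolerance = 1e-3)
  expect_equal(f$pars$q, truth$q, tolerance = 1e-3)
  # duplicating every record must not move a weighted least-squares optimum
  f2 <- fit_individual(rbind(rec, rec), reg, init, pop)
  expect_equal(f2$pars$cl, f$pars$cl, tolerance = 1e-6)
  # neither must permuting the record order
  f3 <- fit_individual(rec[sample(nrow(rec)), ], reg, init, pop)
  expect_equal(unlist(f3$pars), unlist(f$pars), tolerance = 1e-8)
  # too few quantifiable observations flags non-convergence
  f4 <- fit_individual(rec[1:4, ], reg, init, pop)
  expect_false(f4$converged)
})

test_that("the two-stage fit recovers a variability-free population exactly and scales with dose", {
  pop0 <- degenerate_pop()
  ds <- generate_cohort(12, sampling_design("rich"), pop0,
                        clcr_dist = clcr_distribution(122, 30), seed = 5150)
  fit <- two_stage_fit(ds, pop = pop0)
  expect_equal(unname(fit$estimates["theta_cl"]), 16.3, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["theta_vc"]), 19.9, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["theta_vp"]), 18.8, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["theta_q"]), 37.3, tolerance = 1e-3)
  expect_lt(fit$estimates["omega_cl"], 0.01)
  # dose linearity: doubling dose and concentrations leaves CL and V unchanged
  ds2 <- ds
  ds2$data$conc_obs_mg_L <- 2 * ds2$data$conc_obs_mg_L
  ds2$data$dose_mg <- 8000
  ds2$regimen <- dose_regimen(8000, 1 / 3, 6)
  fit2 <- two_stage_fit(ds2, regimen = ds2$regimen, pop = pop0)
  expect_equal(unname(fit2$estimates["theta_cl"]), 16.3, tolerance = 1e-3)
  expect_equal(unname(fit2$estimates["theta_vc"]), 19.9, tolerance = 1e-3)
})

test_that("a cohort without clearance variability yields a near-zero omega_CL", {
  pop <- population_params(bsv_cv = c(cl = 0, vc = 29.6, vp = 67.6, alag = 0.3))
  ds <- generate_cohort(30, sampling_design("rich"), pop, seed = 1234)
  fit <- two_stage_fit(ds, pop = pop)
  expect_lt(unname(fit$estimates["omega_cl"]), 0.05)
})

test_that("the covariate likelihood-ratio statistic is non-negative, calibrated in form, and detects the law", {
  pop <- table2_pop()
  ds <- generate_cohort(48, sampling_design("rich"), pop, seed = 31415)
  lrt <- covariate_lrt(ds)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$threshold, stats::qchisq(0.95, 1))
  expect_true(lrt$significant)
  expect_equal(lrt$gamma, 1, tolerance = 0.35)  # generating exponent is 1
  expect_gt(lrt$r, 0.3)                         # moderate positive correlation
  # with clearance independent of renal function the statistic collapses
  pop0 <- population_params(covariate = "none")
  ds0 <- generate_cohort(48, sampling_design("rich"), pop0, seed = 31416)
  lrt0 <- covariate_lrt(ds0)
  expect_gte(lrt0$statistic, 0)
  expect_lt(lrt0$statistic, lrt$statistic)
})

test_that("bootstrap percentiles match a sort-based oracle and behave at n_boot = 1", {
  pop <- table2_pop()
  ds <- generate_cohort(25, sampling_design("rich"), pop, seed = 2001)
  fit <- two_stage_fit(ds, pop = pop)
  bf <- bootstrap_ci(ds, pop = pop, n_boot = 200, seed = 9, fit = fit)
  expect_true(all(bf$ci["p2.5", ] <= bf$ci["p97.5", ]))
  # independent type-7 percentile computation on the stored replicates
  x <- sort(bf$boot[, "theta_cl"])
  n <- length(x)
  manual <- function(p) {
    h <- (n - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  }
  expect_equal(unname(bf$ci["p2.5", "theta_cl"]), manual(0.025), tolerance = 1e-12)
  expect_equal(unname(bf$ci["p97.5", "theta_cl"]), manual(0.975), tolerance = 1e-12)
  # nominal-level monotonicity of the percentile interval
  q <- stats::quantile(bf$boot[, "theta_cl"], c(0.05, 0.25, 0.75, 0.95))
  expect_true(all(diff(q) >= 0))
  # a single replicate gives a degenerate interval equal to that replicate
  b1 <- bootstrap_ci(ds, pop = pop, n_boot = 1, seed = 10, fit = fit)
  expect_equal(unname(b1$ci["p2.5", ]), unname(b1$ci["p97.5", ]))
})

test_that("goodness of fit: r equals the covariance formula, is 1 noise-free and high under the study error", {
  pop0 <- degenerate_pop()
  ds0 <- generate_cohort(12, sampling_design("rich"), pop0,
                         clcr_dist = clcr_distribution(122, 30), seed = 4)
  g0 <- gof_diagnostics(two_stage_fit(ds0, pop = pop0))
  expect_equal(g0$r, 1, tolerance = 1e-6)
  pop <- table2_pop()
  ds <- generate_cohort(30, sampling_design("rich"), pop, seed = 8080)
  fit <- two_stage_fit(ds, pop = pop)
  g <- gof_diagnostics(fit)
  o <- g$pairs$observed
  p <- g$pairs$predicted
  hand <- sum((o - mean(o)) * (p - mean(p))) /
    sqrt(sum((o - mean(o))^2) * sum((p - mean(p))^2))
  expect_equal(g$r, hand, tolerance = 1e-12)
  expect_gte(g$r, 0.95)
})
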