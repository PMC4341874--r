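test_that("disposition constants satisfy the Vieta identities and match an eigen oracle", {
  p <- table2_params()
  d <- disposition_constants(p)
  expect_equal(d$k10, 16.3 / 19.9)
  expect_equal(d$k12, 37.3 / 19.9)
  expect_equal(d$k21, 37.3 / 18.8)
  local_seed(11)
  for (p in c(list(p), random_pk_params(20))) {
    d <- disposition_constants(p)
    expect_true(d$alpha >= d$beta, info = "alpha is the fast exponent")
    expect_equal(d$alpha + d$beta, d$k10 + d$k12 + d$k21, tolerance = 1e-12)
    expect_equal(d$alpha * d$beta, d$k10 * d$k21, tolerance = 1e-12)
    # negated eigenvalues of the compartment rate matrix
    m <- matrix(c(-(d$k10 + d$k12), d$k21, d$k12, -d$k21), 2, 2, byrow = TRUE)
    expect_equal(sort(-eigen(m)$values), sort(c(d$beta, d$alpha)),
                 tolerance = 1e-10)
  }
  expect_error(pk_params(cl = -1, vc = 19.9, vp = 18.8, q = 37.3), "positive")
})

test_that("single-dose concentration is zero at t = 0, linear in dose, continuous at input end", {
  p <- table2_params()
  expect_identical(conc_single_dose(p, 4000, 1 / 3, 0), 0)
  expect_identical(conc_single_dose(p, 0, 1 / 3, c(0, 1, 5)), c(0, 0, 0))
  expect_error(conc_single_dose(p, 4000, 1 / 3, -1), "non-negative")
  eps <- 1e-12
  jump <- abs(conc_single_dose(p, 4000, 1 / 3, 1 / 3 + eps) -
              conc_single_dose(p, 4000, 1 / 3, 1 / 3 - eps))
  expect_lt(jump, 1e-9)
  expect_equal(conc_single_dose(p, 8000, 1 / 3, 2),
               2 * conc_single_dose(p, 4000, 1 / 3, 2))
})

test_that("closed-form kinetics agree with the ODE reference oracle", {
  p <- table2_params()
  reg <- dose_regimen(4000, 1 / 3, 6, n_doses = 3)
  times <- c(1 / 3, 0.5, 1, 2, 5.9, 6.5, 12.2, 17)
  ode <- ode_reference(p, reg, times)
  cf <- conc_profile(p, reg, times)
  expect_equal(cf$conc_mg_l, ode$conc_mg_l, tolerance = 1e-6)
  # end-of-infusion point of a single dose, the spec's spot check
  reg1 <- dose_regimen(4000, 1 / 3, 6, n_doses = 1)
  p0 <- pk_params(16.3, 19.9, 18.8, 37.3)  # no lag
  o <- ode_reference(p0, reg1, 1 / 3)$conc_mg_l
  expect_equal(conc_single_dose(p0, 4000, 1 / 3, 1 / 3), o, tolerance = 1e-5)
})

test_that("ODE oracle conserves mass during and after the infusion", {
  # independent 3-state integration tracking cumulative elimination
  p <- table2_params()
  d <- disposition_constants(p)
  rate <- 4000 / (1 / 3 + p$alag)
  deriv <- function(t, y, parms) {
    inp <- if (t <= 1 / 3 + p$alag) rate else 0
    list(c(inp - (d$k10 + d$k12) * y[1] + d$k21 * y[2],
           d$k12 * y[1] - d$k21 * y[2],
           d$k10 * y[1]))
  }
  sol <- deSolve::lsoda(c(ac = 0, ap = 0, el = 0), times = c(0, 0.2, 1 / 3 + p$alag, 2, 6),
                        deriv, parms = NULL, atol = 1e-10, rtol = 1e-10)
  administered <- pmin(sol[, "time"], 1 / 3 + p$alag) * rate
  expect_equal(unname(sol[, "ac"] + sol[, "ap"] + sol[, "el"]),
               unname(administered), tolerance = 1e-7)
  # homogeneity in dose (the zero-dose limit): halving the dose halves the curve
  za <- ode_reference(p, dose_regimen(4000, 1 / 3, 6, n_doses = 1), c(1, 3))
  zb <- ode_reference(p, dose_regimen(2000, 1 / 3, 6, n_doses = 1), c(1, 3))
  expect_equal(za$conc_mg_l, 2 * zb$conc_mg_l, tolerance = 1e-8)
})

test_that("steady state equals long superposition and degenerates to a single dose for huge tau", {
  p <- table2_params()
  reg <- study_regimen()
  tt <- seq(0, 6, by = 0.2)
  ss <- conc_steady_state(p, reg, tt)
  reg30 <- dose_regimen(4000, 1 / 3, 6, n_doses = 30)
  sup <- conc_profile(p, reg30, 29 * 6 + tt)$conc_mg_l
  expect_equal(ss, sup, tolerance = 1e-4)
  reg20 <- dose_regimen(4000, 1 / 3, 6, n_doses = 20)
  sup20 <- conc_profile(p, reg20, 19 * 6 + tt)$conc_mg_l
  expect_lt(max(abs(ss - sup20) / ss), 1e-3)
  # no accumulation when tau is enormous
  reg_big <- dose_regimen(4000, 1 / 3, 1000)
  t1 <- c(0.1, 0.3, 1, 4, 9)
  expect_equal(conc_steady_state(p, reg_big, t1),
               conc_single_dose(p, 4000, 1 / 3 + p$alag, t1), tolerance = 1e-9)
  expect_error(conc_steady_state(p, reg, 6.5), "within")
})

test_that("the steady-state trough is the post-input minimum and decreases with CL", {
  reg <- study_regimen()
  p <- table2_params()
  t_end_input <- reg$tinf + p$alag
  post <- seq(t_end_input, 6, length.out = 400)
  cc <- conc_steady_state(p, reg, post)
  expect_equal(which.min(cc), length(cc))
  troughs <- vapply(c(5, 10, 16.3, 25, 40), function(cl) {
    conc_steady_state(pk_params(cl, 19.9, 18.8, 37.3, 0.13), reg, 6)
  }, 0)
  expect_true(all(diff(troughs) < 0))
})

test_that("AUC over one steady-state interval obeys dose/CL mass balance and dose linearity", {
  p <- table2_params()
  reg <- study_regimen()
  expect_equal(auc_ss(p, reg) * p$cl / reg$dose, 1, tolerance = 1e-3)
  expect_equal(auc_ss(p, dose_regimen(8000, 1 / 3, 6)), 2 * auc_ss(p, reg),
               tolerance = 1e-8)
  # Richardson-refined Simpson oracle
  simpson <- function(n) {
    h <- 6 / n
    x <- seq(0, 6, length.out = n + 1)
    y <- conc_steady_state(p, reg, x)
    h / 3 * sum(y * c(1, rep(c(4, 2), length.out = n - 1), 1))
  }
  rich <- (16 * simpson(4096) - simpson(2048)) / 15
  expect_equal(auc_ss(p, reg), rich, tolerance = 1e-3)
})

test_that("closed form tracks the ODE oracle across random parameter sets (property)", {
  local_seed(2024)
  reg <- dose_regimen(4000, 1 / 3, 6, n_doses = 4)
  times <- c(0.25, 0.5, 1.5, 3, 6.2, 11.9, 18, 23.9)
  for (p in random_pk_params(20)) {
    cf <- conc_profile(p, reg, times)$conc_mg_l
    od <- ode_reference(p, reg, times)$conc_mg_l
    expect_lt(max(abs(cf - od) / pmax(od, 1e-9)), 1e-5)
    expect_true(all(cf >= 0))
  }
})

test_that("the Q -> 0 limit reduces to one-compartment zero-order-input kinetics", {
  p <- pk_params(16.3, 19.9, 18.8, 1e-6, 0)
  k <- 16.3 / 19.9
  r0 <- 4000 / (1 / 3)
  cinf <- function(t) (r0 / 16.3) * (1 - exp(-k * pmax(t, 0)))
  t <- seq(0.25, 6, by = 0.25)
  one_cpt <- cinf(t) - cinf(t - 1 / 3)
  expect_equal(conc_single_dose(p, 4000, 1 / 3, t), one_cpt, tolerance = 1e-4)
})

test_that("infusion-lag modes place the input as documented", {
  reg <- study_regimen()
  p <- pk_params(16.3, 19.9, 18.8, 37.3, alag = 0.2)
  # extended: input runs to tinf + alag, so concentration still rises there
  cc <- conc_steady_state(p, reg, c(reg$tinf, reg$tinf + 0.19))
  expect_gt(cc[2], cc[1])
  # delay: profile is the no-lag profile shifted by alag
  p0 <- pk_params(16.3, 19.9, 18.8, 37.3, alag = 0)
  t <- seq(0.3, 5.5, by = 0.4)
  expect_equal(conc_steady_state(p, reg, t, alag_mode = "delay"),
               conc_steady_state(p0, reg, t - 0.2), tolerance = 1e-10)
  # overlapping effective infusion is rejected
  expect_error(conc_profile(pk_params(16.3, 19.9, 18.8, 37.3, alag = 5.9),
                            dose_regimen(4000, 1 / 3, 6, n_doses = 2), c(0, 1)),
               "overlap")
})
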