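# Closed-form two-compartment kinetics with zero-order (infusion) input.
#
# All formulas work on the "infinite infusion" decomposition: a finite
# zero-order input of duration T at rate R0 equals an infusion switched on at
# t = 0 forever minus one switched on at t = T.  With hybrid exponents
# alpha >= beta and coefficients
#   A = (alpha - k21) / (alpha (alpha - beta)),
#   B = (k21  - beta) / (beta  (alpha - beta)),
# the running-infusion central concentration is
#   Cinf(t) = (R0 / Vc) [ A (1 - e^{-alpha t}) + B (1 - e^{-beta t}) ].
# Both A and B are non-negative (beta <= k21 <= alpha), so the post-input
# washout is a sum of decaying exponentials with non-negative coefficients.

.infusion_coefs <- function(p) {
  d <- disposition_constants(p)
  ab <- d$alpha - d$beta
  list(alpha = d$alpha, beta = d$beta,
       A = (d$alpha - d$k21) / (d$alpha * ab),
       B = (d$k21 - d$beta) / (d$beta * ab))
}

# Cinf(t)*Vc/R0 for vector t (t < 0 treated as 0: infusion not yet started)
.cinf_unit <- function(co, t) {
  t <- pmax(t, 0)
  co$A * (1 - exp(-co$alpha * t)) + co$B * (1 - exp(-co$beta * t))
}

#' Concentration after a single zero-order input
#'
#' Central-compartment concentration at time `t` after the start of a single
#' zero-order drug input of total amount `dose` delivered over `t_in` hours.
#' The profile rises during the input phase and washes out biexponentially
#' afterwards; it is continuous at `t = t_in` and zero at `t = 0`.
#'
#' @param p A [pk_params()] object (the `alag` field is not used here; lag
#'   semantics are applied by [conc_profile()] and [conc_steady_state()]).
#' @param dose Input amount (mg), >= 0.
#' @param t_in Effective zero-order input duration (h), > 0.
#' @param t Time since input start (h); vectorised, all >= 0.
#' @return Concentration(s), mg/L.
#' @examples
#' p <- pk_params(16.3, 19.9, 18.8, 37.3)
#' conc_single_dose(p, dose = 4000, t_in = 1 / 3, t = c(0, 1 / 3, 1, 6))
#' @export
conc_single_dose <- function(p, dose, t_in, t) {
  stopifnot(inherits(p, "pk_params"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0) {
    stop("'dose' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(t_in) || length(t_in) != 1L || t_in <= 0) {
    stop("'t_in' must be a single positive number", call. = FALSE)
  }
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (dose == 0) return(numeric(length(t)) )
  co <- .infusion_coefs(p)
  r0 <- dose / t_in
  (r0 / p$vc) * (.cinf_unit(co, t) - .cinf_unit(co, t - t_in))
}

# Effective input geometry under the two infusion-lag conventions.
# "extended": the full dose enters over tinf + alag starting at the dose time
#   (residual line drug keeps running in after pump stop).
# "delay": the input starts alag after the dose time and runs for tinf.
.effective_input <- function(p, regimen, alag_mode) {
  alag_mode <- match.arg(alag_mode, c("extended", "delay"))
  if (alag_mode == "extended") {
    list(t_in = regimen$tinf + p$alag, start = 0)
  } else {
    list(t_in = regimen$tinf, start = p$alag)
  }
}

.check_no_overlap <- function(p, regimen, alag_mode) {
  inp <- .effective_input(p, regimen, alag_mode)
  if (inp$start + inp$t_in > regimen$tau) {
    stop("effective infusion (tinf + alag = ", inp$start + inp$t_in,
         " h) overlaps the next dose (tau = ", regimen$tau, " h)",
         call. = FALSE)
  }
  inp
}

#' Multiple-dose concentration profile by superposition
#'
#' Superposes [conc_single_dose()] over all administered doses of a finite
#' regimen. Each dose's effective zero-order input is placed according to the
#' infusion-lag convention (`alag_mode`).
#'
#' @param p A [pk_params()] object.
#' @param regimen A [dose_regimen()] with finite `n_doses` (use
#'   [conc_steady_state()] for the steady-state profile).
#' @param times Sampling times (h) since the first dose start, non-negative
#'   and increasing.
#' @param alag_mode `"extended"` (default: the dose enters over
#'   `tinf + alag`) or `"delay"` (input starts `alag` after the dose time).
#' @return A data.frame with columns `time_h` and `conc_mg_l`.
#' @export
conc_profile <- function(p, regimen, times, alag_mode = "extended") {
  stopifnot(inherits(p, "pk_params"), inherits(regimen, "dose_regimen"))
  if (!is.finite(regimen$n_doses)) {
    stop("'regimen' must have finite n_doses; use conc_steady_state() for steady state",
         call. = FALSE)
  }
  if (any(times < 0) || is.unsorted(times)) {
    stop("'times' must be non-negative and increasing", call. = FALSE)
  }
  inp <- .check_no_overlap(p, regimen, alag_mode)
  conc <- numeric(length(times))
  for (k in seq_len(regimen$n_doses)) {
    t0 <- (k - 1) * regimen$tau + inp$start
    on <- times >= t0
    if (!any(on)) break
    conc[on] <- conc[on] +
      conc_single_dose(p, regimen$dose, inp$t_in, times[on] - t0)
  }
  data.frame(time_h = times, conc_mg_l = conc)
}

#' Steady-state concentration within one dosing interval
#'
#' Closed-form steady-state concentration, obtained by applying the
#' geometric-series accumulation factor `1 / (1 - exp(-lambda * tau))` to each
#' exponential washout term of the single-dose solution.
#'
#' @inheritParams conc_profile
#' @param t Time(s) within the dosing interval, 0 <= t <= tau, measured from
#'   the start of an infusion at steady state.
#' @return Concentration(s), mg/L.
#' @examples
#' p <- pk_params(16.3, 19.9, 18.8, 37.3, alag = 0.13)
#' conc_steady_state(p, standard_regimen(), t = c(0, 1 / 3, 3, 6))
#' @export
conc_steady_state <- function(p, regimen, t, alag_mode = "extended") {
  stopifnot(inherits(p, "pk_params"), inherits(regimen, "dose_regimen"))
  if (any(t < 0 | t > regimen$tau)) {
    stop("'t' must lie within [0, tau]", call. = FALSE)
  }
  inp <- .check_no_overlap(p, regimen, alag_mode)
  # the delayed-input profile is the phase-shifted extended-start profile
  tt <- (t - inp$start) %% regimen$tau
  co <- .infusion_coefs(p)
  r0 <- regimen$dose / inp$t_in
  tau <- regimen$tau
  acc_a <- exp(-co$alpha * tau) / (1 - exp(-co$alpha * tau))
  acc_b <- exp(-co$beta * tau) / (1 - exp(-co$beta * tau))
  single <- .cinf_unit(co, tt) - .cinf_unit(co, tt - inp$t_in)
  tail_a <- co$A * (1 - exp(-co$alpha * inp$t_in)) * exp(-co$alpha * (tt - inp$t_in)) * acc_a
  tail_b <- co$B * (1 - exp(-co$beta * inp$t_in)) * exp(-co$beta * (tt - inp$t_in)) * acc_b
  (r0 / p$vc) * (single + tail_a + tail_b)
}

#' Steady-state area under the curve over one dosing interval
#'
#' Adaptive quadrature of [conc_steady_state()] over `[0, tau]`, split at the
#' input-phase boundary. For a linear model this must equal `dose / CL`
#' (mass balance), which the test suite asserts.
#'
#' @inheritParams conc_steady_state
#' @param rel_tol Relative quadrature tolerance.
#' @return AUC over one interval at steady state, mg.h/L.
#' @export
auc_ss <- function(p, regimen, alag_mode = "extended", rel_tol = 1e-10) {
  inp <- .check_no_overlap(p, regimen, alag_mode)
  f <- function(t) conc_steady_state(p, regimen, t, alag_mode = alag_mode)
  brk <- min(inp$start + inp$t_in, regimen$tau)
  a1 <- stats::integrate(f, 0, brk, rel.tol = rel_tol, abs.tol = 0)
  a2 <- stats::integrate(f, brk, regimen$tau, rel.tol = rel_tol, abs.tol = 0)
  a1$value + a2$value
}

#' Numerical ODE reference solution
#'
#' Independent oracle for the closed-form kinetics: integrates the
#' two-compartment amount equations
#' `dAc/dt = input(t) - (k10 + k12) Ac + k21 Ap`,
#' `dAp/dt = k12 Ac - k21 Ap`
#' piecewise between input on/off boundaries with `deSolve::lsoda` at tight
#' tolerance, and returns `Ac / Vc`.
#'
#' @inheritParams conc_profile
#' @param atol,rtol Solver tolerances.
#' @return A data.frame with columns `time_h` and `conc_mg_l`.
#' @export
ode_reference <- function(p, regimen, times, alag_mode = "extended",
                          atol = 1e-11, rtol = 1e-11) {
  stopifnot(inherits(p, "pk_params"), inherits(regimen, "dose_regimen"))
  if (!is.finite(regimen$n_doses)) {
    stop("'regimen' must have finite n_doses for the ODE reference", call. = FALSE)
  }
  if (any(times < 0) || is.unsorted(times)) {
    stop("'times' must be non-negative and increasing", call. = FALSE)
  }
  inp <- .check_no_overlap(p, regimen, alag_mode)
  d <- disposition_constants(p)
  rate <- regimen$dose / inp$t_in
  starts <- (seq_len(regimen$n_doses) - 1) * regimen$tau + inp$start
  stops <- starts + inp$t_in
  t_end <- max(times, stops)
  bounds <- sort(unique(c(0, starts, stops, t_end)))
  bounds <- bounds[bounds <= t_end]

  deriv <- function(t, y, parms) {
    list(c(parms$inrate - (d$k10 + d$k12) * y[1] + d$k21 * y[2],
           d$k12 * y[1] - d$k21 * y[2]))
  }
  state <- c(ac = 0, ap = 0)
  out_t <- numeric(0)
  out_c <- numeric(0)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    seg_rate <- if (any(lo >= starts - 1e-12 & hi <= stops + 1e-12)) rate else 0
    inner <- times[times > lo & times <= hi]
    tt <- sort(unique(c(lo, inner, hi)))
    sol <- deSolve::lsoda(y = state, times = tt, func = deriv,
                          parms = list(inrate = seg_rate),
                          atol = atol, rtol = rtol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed on segment [", lo, ", ", hi, "]", call. = FALSE)
    }
    state <- c(ac = unname(sol[nrow(sol), "ac"]),
               ap = unname(sol[nrow(sol), "ap"]))
    keep <- sol[, "time"] %in% inner
    out_t <- c(out_t, sol[keep, "time"])
    out_c <- c(out_c, sol[keep, "ac"] / p$vc)
  }
  if (any(times == 0)) {
    out_t <- c(0, out_t)
    out_c <- c(0, out_c)
  }
  ord <- order(out_t)
  data.frame(time_h = out_t[ord], conc_mg_l = out_c[ord])
}
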