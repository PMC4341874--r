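#' Population pharmacokinetic parameters
#'
#' Fixed effects (typical values), between-subject variability (BSV) and
#' residual-error parameters of the final piperacillin population model.
#' Typical clearance `theta_cl` is normalised to a creatinine clearance of
#' 100 ml/min: the covariate law is `TVCL = theta_cl * clcr / 100`.
#'
#' BSV is an exponential (log-normal) model. Reported percent coefficients of
#' variation are mapped to log-scale SDs as `omega = cv / 100`
#' (`cv_mapping = "approx"`, the standard pharmacometric reporting
#' convention) or exactly as `omega = sqrt(log(1 + (cv/100)^2))`
#' (`cv_mapping = "exact"`). The ALAG BSV value is taken as an omega
#' directly. No BSV is carried on Q (none identified).
#'
#' @param theta_cl Typical clearance at CLCR 100 ml/min (L/h).
#' @param theta_vc,theta_vp Typical central / peripheral volumes (L).
#' @param theta_q Typical intercompartmental clearance (L/h).
#' @param theta_alag Typical infusion lag (h).
#' @param bsv_cv Named numeric vector of BSV magnitudes for `cl`, `vc`, `vp`
#'   (percent CV) and `alag` (log-scale SD).
#' @param ruv_prop_cv Proportional residual-error CV (fraction, e.g. 0.01).
#' @param ruv_add_sd Additive residual-error SD (mg/L).
#' @param covariate `"clcr_linear"` (TVCL proportional to CLCR/100) or
#'   `"none"` (clearance independent of renal function; used for null
#'   simulations).
#' @param cv_mapping How percent CVs map to omegas (see Details).
#'
#' @return An object of class `population_params`.
#' @examples
#' population_params()  # the final-model defaults
#' @export
population_params <- function(theta_cl = 16.3,
                              theta_vc = 19.9,
                              theta_vp = 18.8,
                              theta_q = 37.3,
                              theta_alag = 0.13,
                              bsv_cv = c(cl = 56.0, vc = 29.6, vp = 67.6, alag = 0.3),
                              ruv_prop_cv = 0.01,
                              ruv_add_sd = 0.3,
                              covariate = c("clcr_linear", "none"),
                              cv_mapping = c("approx", "exact")) {
  covariate <- match.arg(covariate)
  cv_mapping <- match.arg(cv_mapping)
  for (nm in c("theta_cl", "theta_vc", "theta_vp", "theta_q")) {
    if (get(nm) <= 0) stop("'", nm, "' must be positive", call. = FALSE)
  }
  if (theta_alag < 0) stop("'theta_alag' must be >= 0", call. = FALSE)
  need <- c("cl", "vc", "vp", "alag")
  if (!all(need %in% names(bsv_cv)) || any(bsv_cv[need] < 0)) {
    stop("'bsv_cv' must name non-negative cl, vc, vp, alag entries", call. = FALSE)
  }
  if (ruv_prop_cv < 0 || ruv_add_sd < 0) {
    stop("residual-error parameters must be non-negative", call. = FALSE)
  }
  cv2om <- function(cv) {
    if (cv_mapping == "approx") cv / 100 else sqrt(log(1 + (cv / 100)^2))
  }
  omega <- c(cl = cv2om(bsv_cv[["cl"]]),
             vc = cv2om(bsv_cv[["vc"]]),
             vp = cv2om(bsv_cv[["vp"]]),
             alag = bsv_cv[["alag"]])  # reported directly on the omega scale
  structure(list(theta_cl = theta_cl, theta_vc = theta_vc,
                 theta_vp = theta_vp, theta_q = theta_q,
                 theta_alag = theta_alag,
                 omega = omega,
                 ruv_prop_cv = ruv_prop_cv, ruv_add_sd = ruv_add_sd,
                 covariate = covariate, cv_mapping = cv_mapping),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population PK parameters\n")
  cat(sprintf("  theta: CL %.3g L/h (at CLCR 100), Vc %.3g L, Vp %.3g L, Q %.3g L/h, ALAG %.3g h\n",
              x$theta_cl, x$theta_vc, x$theta_vp, x$theta_q, x$theta_alag))
  cat(sprintf("  omega: CL %.3g, Vc %.3g, Vp %.3g, ALAG %.3g (log-scale SD)\n",
              x$omega[["cl"]], x$omega[["vc"]], x$omega[["vp"]], x$omega[["alag"]]))
  cat(sprintf("  RUV: %.3g proportional CV + %.3g mg/L additive SD\n",
              x$ruv_prop_cv, x$ruv_add_sd))
  cat("  covariate on CL:", x$covariate, "\n")
  invisible(x)
}

#' Typical (covariate-adjusted) clearance
#'
#' The renal-function covariate law of the final model: typical clearance is
#' proportional to measured creatinine clearance normalised to 100 ml/min.
#'
#' @param theta_cl Typical clearance at CLCR 100 ml/min (L/h).
#' @param clcr Measured creatinine clearance (ml/min), > 0; vectorised.
#' @return Typical clearance(s), L/h.
#' @examples
#' typical_clearance(16.3, 122)  # 16.3 * 1.22
#' @export
typical_clearance <- function(theta_cl, clcr) {
  if (any(!is.finite(clcr)) || any(clcr <= 0)) {
    stop("'clcr' must be positive", call. = FALSE)
  }
  theta_cl * clcr / 100
}

# Typical individual values for a population and covariate vector; matrix of
# typicals with one row per subject (used by sampling and estimation).
.typical_values <- function(pop, clcr) {
  tvcl <- if (pop$covariate == "clcr_linear") {
    typical_clearance(pop$theta_cl, clcr)
  } else {
    rep(pop$theta_cl, length(clcr))
  }
  data.frame(cl = tvcl,
             vc = rep(pop$theta_vc, length(clcr)),
             vp = rep(pop$theta_vp, length(clcr)),
             q = rep(pop$theta_q, length(clcr)),
             alag = rep(pop$theta_alag, length(clcr)))
}

# Draw n subjects' parameters as a data.frame (vectorised core of
# sample_individual); etas optionally supplied for common-random-number reuse.
.sample_parameters <- function(pop, clcr, etas = NULL) {
  n <- length(clcr)
  tv <- .typical_values(pop, clcr)
  if (is.null(etas)) {
    etas <- cbind(cl = stats::rnorm(n, 0, pop$omega[["cl"]]),
                  vc = stats::rnorm(n, 0, pop$omega[["vc"]]),
                  vp = stats::rnorm(n, 0, pop$omega[["vp"]]),
                  alag = stats::rnorm(n, 0, pop$omega[["alag"]]))
  }
  data.frame(cl = tv$cl * exp(etas[, "cl"]),
             vc = tv$vc * exp(etas[, "vc"]),
             vp = tv$vp * exp(etas[, "vp"]),
             q = tv$q,
             alag = tv$alag * exp(etas[, "alag"]),
             clcr = clcr)
}

#' Sample one individual from the population model
#'
#' Applies the exponential BSV model: each parameter with a variability term
#' is `typical * exp(eta)`, `eta ~ N(0, omega^2)` independently. The typical
#' clearance is covariate-adjusted via [typical_clearance()]; Q carries no
#' BSV.
#'
#' @param pop A [population_params()] object.
#' @param clcr The subject's measured creatinine clearance (ml/min).
#' @return A [pk_params()] object.
#' @export
sample_individual <- function(pop, clcr) {
  stopifnot(inherits(pop, "population_params"), length(clcr) == 1L)
  s <- .sample_parameters(pop, clcr)
  pk_params(cl = s$cl, vc = s$vc, vp = s$vp, q = s$q, alag = s$alag)
}

#' Apply the combined residual-error model to a true concentration
#'
#' Observation model `y = c (1 + eps_p) + eps_a` with
#' `eps_p ~ N(0, prop_cv^2)` and `eps_a ~ N(0, add_sd^2)`; negative results
#' are truncated to zero. Vectorised over `conc_true`.
#'
#' @param conc_true True (model) concentration(s), mg/L, >= 0.
#' @param pop A [population_params()] object supplying the error magnitudes.
#' @return Observed concentration(s), mg/L.
#' @export
observe <- function(conc_true, pop) {
  stopifnot(inherits(pop, "population_params"))
  if (any(conc_true < 0)) stop("'conc_true' must be non-negative", call. = FALSE)
  n <- length(conc_true)
  y <- conc_true * (1 + stats::rnorm(n, 0, pop$ruv_prop_cv)) +
    stats::rnorm(n, 0, pop$ruv_add_sd)
  pmax(y, 0)
}
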