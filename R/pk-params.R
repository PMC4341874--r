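#' Individual pharmacokinetic parameters
#'
#' Bundle of one subject's two-compartment disposition parameters. Units are
#' litres and hours throughout: clearances in L/h, volumes in L, the infusion
#' lag `alag` in h. The lag describes residual drug flushed through the IV
#' line after the pump stops and is modelled as part of the zero-order input
#' (see [conc_single_dose()]).
#'
#' @param cl Drug clearance (L/h), > 0.
#' @param vc Central volume of distribution (L), > 0.
#' @param vp Peripheral volume of distribution (L), > 0.
#' @param q Intercompartmental clearance (L/h), > 0.
#' @param alag Infusion lag (h), >= 0.
#'
#' @return An object of class `pk_params` (named list).
#' @examples
#' pk_params(cl = 16.3, vc = 19.9, vp = 18.8, q = 37.3, alag = 0.13)
#' @export
pk_params <- function(cl, vc, vp, q, alag = 0) {
  for (nm in c("cl", "vc", "vp", "q")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
    }
  }
  if (!is.numeric(alag) || length(alag) != 1L || !is.finite(alag) || alag < 0) {
    stop("'alag' must be a single non-negative finite number", call. = FALSE)
  }
  structure(list(cl = cl, vc = vc, vp = vp, q = q, alag = alag),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Individual PK parameters (two-compartment)\n")
  cat(sprintf("  CL  %8.3f L/h\n  Vc  %8.3f L\n  Vp  %8.3f L\n  Q   %8.3f L/h\n  ALAG%8.3f h\n",
              x$cl, x$vc, x$vp, x$q, x$alag))
  invisible(x)
}

#' Intermittent-infusion dose regimen
#'
#' @param dose Drug amount per administration (mg), > 0.
#' @param tinf Pump infusion duration (h), 0 < tinf <= tau.
#' @param tau Interdose interval (h), > 0.
#' @param n_doses Number of administered doses (>= 1), or `Inf` for steady
#'   state.
#'
#' @return An object of class `dose_regimen`.
#' @examples
#' # 4,000 mg piperacillin over 20 min every 6 h (steady state)
#' dose_regimen(dose = 4000, tinf = 1 / 3, tau = 6)
#' @export
dose_regimen <- function(dose, tinf, tau, n_doses = Inf) {
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0) {
    stop("'dose' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("'tau' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(tinf) || length(tinf) != 1L || tinf <= 0 || tinf > tau) {
    stop("'tinf' must satisfy 0 < tinf <= tau", call. = FALSE)
  }
  if (!(identical(n_doses, Inf) ||
        (is.numeric(n_doses) && length(n_doses) == 1L && n_doses >= 1 &&
         n_doses == floor(n_doses)))) {
    stop("'n_doses' must be a positive integer or Inf (steady state)", call. = FALSE)
  }
  structure(list(dose = dose, tinf = tinf, tau = tau, n_doses = n_doses),
            class = "dose_regimen")
}

#' Standard piperacillin study regimen
#'
#' 4,000 mg piperacillin (the piperacillin component of 4.5 g
#' piperacillin-tazobactam, 8:1 formulation) infused over 20 minutes every
#' 6 hours at steady state.
#'
#' @param dose Piperacillin dose per administration (mg).
#' @return A [dose_regimen()].
#' @export
standard_regimen <- function(dose = 4000) {
  dose_regimen(dose = dose, tinf = 1 / 3, tau = 6, n_doses = Inf)
}

#' Micro and hybrid disposition constants of the two-compartment model
#'
#' Converts clearances and volumes to first-order micro rate constants
#' (k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp) and the hybrid exponents
#' alpha >= beta, the negated eigenvalues of the compartment rate matrix,
#' i.e. the roots of s^2 - (k10 + k12 + k21) s + k10 k21 = 0.
#'
#' @param p A [pk_params()] object.
#' @return A list with `k10`, `k12`, `k21`, `alpha`, `beta` (all 1/h).
#' @examples
#' disposition_constants(pk_params(16.3, 19.9, 18.8, 37.3))
#' @export
disposition_constants <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  k10 <- p$cl / p$vc
  k12 <- p$q / p$vc
  k21 <- p$q / p$vp
  s <- k10 + k12 + k21
  # discriminant is always > 0 for positive rate constants
  disc <- sqrt(s * s - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}
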