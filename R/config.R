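# JSON run configuration tying the pipeline stages together. The defaults
# reproduce the study configuration: 4,000 mg piperacillin over 20 min every
# 6 h, MIC grid 2-64 mg/L, creatinine clearance 10-300 ml/min in 10-ml/min
# steps, 50%/100% fT>MIC targets, sparse clinical sampling, LLOQ 1 mg/L.

#' Default run configuration
#'
#' @return A nested list with blocks `population`, `regimen`, `grid`,
#'   `simulation` and `cohort`; see [read_run_config()] for the JSON form.
#' @export
default_config <- function() {
  list(
    population = list(
      theta_cl = 16.3, theta_vc = 19.9, theta_vp = 18.8, theta_q = 37.3,
      theta_alag = 0.13,
      bsv_cv = list(cl = 56.0, vc = 29.6, vp = 67.6, alag = 0.3),
      ruv_prop_cv = 0.01, ruv_add_sd = 0.3,
      covariate = "clcr_linear", cv_mapping = "approx"
    ),
    regimen = list(dose_mg = 4000, tinf_h = 1 / 3, tau_h = 6),
    grid = list(mic = c(2, 4, 8, 16, 32, 64),
                clcr = list(from = 10, to = 300, by = 10),
                targets = c(0.5, 1.0)),
    simulation = list(n_subjects = 10000L, seed = 20150130L,
                      common_random_numbers = TRUE, alag_mode = "extended"),
    cohort = list(n = 48L, design = "sparse",
                  clcr = list(mean = 122, sd = 59.2, lower = 20, upper = 350),
                  lloq = 1.0),
    fit = list(n_boot = 1000L, min_converged = 10L)
  )
}

# recursively overlay user values on the defaults
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read and validate a JSON run configuration
#'
#' Unspecified fields fall back to [default_config()].
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return A validated config list (class `pippk_config`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- .merge_config(cfg, user)
  }
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A config list.
#' @return The config, classed `pippk_config`; errors on invalid fields.
#' @export
validate_config <- function(cfg) {
  r <- cfg$regimen
  if (!is.numeric(r$dose_mg) || r$dose_mg <= 0) stop("regimen.dose_mg must be > 0", call. = FALSE)
  if (!is.numeric(r$tinf_h) || r$tinf_h <= 0 || r$tinf_h > r$tau_h) {
    stop("regimen.tinf_h must satisfy 0 < tinf_h <= tau_h", call. = FALSE)
  }
  g <- cfg$grid
  if (length(g$mic) == 0L || any(g$mic <= 0)) stop("grid.mic must be non-empty and positive", call. = FALSE)
  if (any(g$targets <= 0 | g$targets > 1)) stop("grid.targets must be in (0, 1]", call. = FALSE)
  if (g$clcr$from <= 0 || g$clcr$to < g$clcr$from || g$clcr$by <= 0) {
    stop("grid.clcr range is invalid", call. = FALSE)
  }
  s <- cfg$simulation
  if (!is.numeric(s$n_subjects) || s$n_subjects < 1) stop("simulation.n_subjects must be >= 1", call. = FALSE)
  if (!is.numeric(s$seed)) stop("simulation.seed must be an integer", call. = FALSE)
  if (cfg$cohort$n < 1) stop("cohort.n must be >= 1", call. = FALSE)
  if (cfg$cohort$lloq < 0) stop("cohort.lloq must be >= 0", call. = FALSE)
  # population block must construct
  .config_population(cfg)
  structure(cfg, class = c("pippk_config", "list"))
}

.config_population <- function(cfg) {
  p <- cfg$population
  population_params(theta_cl = p$theta_cl, theta_vc = p$theta_vc,
                    theta_vp = p$theta_vp, theta_q = p$theta_q,
                    theta_alag = p$theta_alag,
                    bsv_cv = unlist(p$bsv_cv),
                    ruv_prop_cv = p$ruv_prop_cv, ruv_add_sd = p$ruv_add_sd,
                    covariate = p$covariate, cv_mapping = p$cv_mapping)
}

.config_regimen <- function(cfg) {
  dose_regimen(dose = cfg$regimen$dose_mg, tinf = cfg$regimen$tinf_h,
               tau = cfg$regimen$tau_h, n_doses = Inf)
}

.config_clcr_values <- function(cfg) {
  seq(cfg$grid$clcr$from, cfg$grid$clcr$to, by = cfg$grid$clcr$by)
}
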