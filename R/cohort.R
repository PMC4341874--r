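# Synthetic study cohorts: the study design this package emulates is a
# single steady-state dosing interval of 4,000 mg piperacillin infused over
# 20 min every 6 h, sampled predose and at 20, 40, 60, 210 and 360 min, with
# an assay LLOQ of 1 mg/L and measured creatinine clearance ~ 122 (SD 59.2)
# ml/min across subjects.

#' Sampling design within one dosing interval
#'
#' @param label `"sparse"` (the clinical design: predose, 20, 40, 60, 210,
#'   360 min) or `"rich"` (12 points over the interval, used for individual
#'   parameter estimation).
#' @param tau Interdose interval (h), used only for validation.
#' @return Numeric vector of sample times (h), starting at 0 (predose, i.e.
#'   the steady-state trough).
#' @export
sampling_design <- function(label = c("sparse", "rich"), tau = 6) {
  label <- match.arg(label)
  times <- switch(label,
    sparse = c(0, 20, 40, 60, 210, 360) / 60,
    rich = c(0, 1 / 6, 1 / 3, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6)
  )
  stopifnot(all(times >= 0), all(times <= tau), !is.unsorted(times))
  structure(times, label = label)
}

#' Creatinine clearance distribution of the simulated cohort
#'
#' Log-normal with moments matched to the requested arithmetic mean and SD,
#' truncated by rejection to the given bounds.
#'
#' @param mean,sd Arithmetic mean and SD (ml/min) of the untruncated law.
#' @param lower,upper Truncation bounds (ml/min).
#' @return An object of class `clcr_distribution`.
#' @export
clcr_distribution <- function(mean = 122, sd = 59.2, lower = 20, upper = 350) {
  stopifnot(mean > 0, sd > 0, lower > 0, lower < upper)
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "clcr_distribution")
}

#' Sample creatinine clearance values
#'
#' @param n Number of draws.
#' @param dist A [clcr_distribution()].
#' @param seed Optional integer seed.
#' @return Numeric vector (ml/min), all within the truncation bounds.
#' @export
sample_clcr <- function(n, dist = clcr_distribution(), seed = NULL) {
  stopifnot(inherits(dist, "clcr_distribution"), n >= 1)
  cv2 <- (dist$sd / dist$mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(dist$mean) - sdlog^2 / 2
  .with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rlnorm(n, meanlog, sdlog)
      out <- c(out, x[x >= dist$lower & x <= dist$upper])
    }
    out[seq_len(n)]
  })
}

#' Generate a virtual study cohort
#'
#' Per subject: draw a creatinine clearance, sample individual parameters
#' from the population model, evaluate the steady-state profile at the design
#' times, apply the residual-error model and flag observations below the
#' limit of quantification. True per-subject parameters are retained for
#' parameter-recovery work.
#'
#' @param n Number of subjects.
#' @param design A [sampling_design()] (or numeric vector of times in h).
#' @param pop A [population_params()] object.
#' @param regimen A [dose_regimen()].
#' @param clcr_dist A [clcr_distribution()].
#' @param lloq Lower limit of quantification (mg/L).
#' @param seed Optional integer seed.
#' @param alag_mode Infusion-lag convention.
#' @return An object of class `cohort_dataset`: a list with `data` (one row
#'   per observation: `subject_id`, `time_h`, `conc_obs_mg_L`, `blq`,
#'   `clcr_ml_min`, `dose_mg`, `tinf_h`, `tau_h`), `truth` (one row per
#'   subject: true `cl`, `vc`, `vp`, `q`, `alag`, `clcr`), `regimen`,
#'   `lloq`, `design`.
#' @export
generate_cohort <- function(n, design = sampling_design("sparse"),
                            pop = population_params(),
                            regimen = standard_regimen(),
                            clcr_dist = clcr_distribution(),
                            lloq = 1.0, seed = NULL,
                            alag_mode = "extended") {
  stopifnot(n >= 1, inherits(pop, "population_params"),
            inherits(regimen, "dose_regimen"))
  times <- as.numeric(design)
  stopifnot(all(times >= 0), all(times <= regimen$tau))
  .with_seed(seed, {
    clcr <- sample_clcr(n, clcr_dist)
    par <- .sample_parameters(pop, clcr)
    cm <- .ss_conc_matrix(par, regimen, times, alag_mode)  # times x subjects
    conc_true <- as.vector(cm)
    conc_obs <- observe(conc_true, pop)
    dat <- data.frame(
      subject_id = rep(seq_len(n), each = length(times)),
      time_h = rep(times, times = n),
      conc_obs_mg_L = conc_obs,
      blq = conc_obs < lloq,
      clcr_ml_min = rep(clcr, each = length(times)),
      dose_mg = regimen$dose, tinf_h = regimen$tinf, tau_h = regimen$tau
    )
    truth <- cbind(subject_id = seq_len(n), par)
    structure(list(data = dat, truth = truth, regimen = regimen,
                   lloq = lloq, design = times),
              class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d observations (%d BLQ < %.3g mg/L)\n",
              nrow(x$truth), nrow(x$data), sum(x$data$blq), x$lloq))
  invisible(x)
}

#' Steady-state trough attainment against an MIC
#'
#' Count and fraction of subjects whose predose (trough) observation exceeds
#' the MIC. A trough above the MIC over a full interval at steady state
#' implies 100% fT>MIC. BLQ troughs count as non-attainers; subjects with no
#' predose record are excluded from the denominator.
#'
#' @param ds A [cohort_dataset()] (from [generate_cohort()]).
#' @param mic Threshold MIC (mg/L); default 16, the susceptibility breakpoint
#'   for *P. aeruginosa*.
#' @return A list with `count`, `n` and `fraction`.
#' @export
trough_attainment <- function(ds, mic = 16) {
  stopifnot(inherits(ds, "cohort_dataset"))
  tr <- ds$data[ds$data$time_h == 0, ]
  if (nrow(tr) == 0L) stop("no predose (t = 0) records in dataset", call. = FALSE)
  attain <- !tr$blq & tr$conc_obs_mg_L > mic
  list(count = sum(attain), n = nrow(tr), fraction = mean(attain))
}

#' Mean concentration profiles by creatinine-clearance quartile
#'
#' Splits subjects at the empirical creatinine-clearance quartiles (linear
#' interpolation between order statistics, `stats::quantile` type 7) and
#' summarises the mean log10 concentration at each design time per group.
#' BLQ observations enter the mean as `lloq / 2`.
#'
#' @param ds A [cohort_dataset()].
#' @return A data.frame with `quartile` (1 = lowest clearance), `time_h`,
#'   `mean_log10_conc`, `n_subjects`, `n_blq`.
#' @export
summarize_by_quartile <- function(ds) {
  stopifnot(inherits(ds, "cohort_dataset"))
  if (nrow(ds$truth) < 4L) stop("need at least 4 subjects", call. = FALSE)
  clcr <- ds$truth$clcr[match(ds$data$subject_id, ds$truth$subject_id)]
  brk <- stats::quantile(ds$truth$clcr, c(0.25, 0.5, 0.75), type = 7)
  qt <- findInterval(clcr, brk, left.open = TRUE) + 1L
  conc <- ifelse(ds$data$blq, ds$lloq / 2, ds$data$conc_obs_mg_L)
  agg <- stats::aggregate(
    cbind(mean_log10_conc = log10(pmax(conc, .Machine$double.eps))),
    by = list(quartile = qt, time_h = ds$data$time_h), FUN = mean)
  nsub <- tapply(ds$truth$clcr,
                 findInterval(ds$truth$clcr, brk, left.open = TRUE) + 1L,
                 length)
  nblq <- stats::aggregate(cbind(n_blq = ds$data$blq),
                           by = list(quartile = qt, time_h = ds$data$time_h),
                           FUN = sum)
  out <- merge(agg, nblq, by = c("quartile", "time_h"))
  out$n_subjects <- as.integer(nsub[as.character(out$quartile)])
  out[order(out$quartile, out$time_h), ]
}

#' Write / read a cohort dataset as CSV
#'
#' The observation table goes to `path`; the per-subject truth table to a
#' `*_truth.csv` sidecar (if `truth_path` is not given).
#'
#' @param ds A [cohort_dataset()].
#' @param path Observation CSV path.
#' @param truth_path Truth sidecar path (default derived from `path`).
#' @param digits Significant digits for numeric columns (NULL = full).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ds, path, truth_path = NULL, digits = 6) {
  stopifnot(inherits(ds, "cohort_dataset"))
  if (is.null(truth_path)) truth_path <- sub("\\.csv$", "_truth.csv", path)
  fmt <- function(df) {
    if (is.null(digits)) return(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = digits)
    df
  }
  utils::write.csv(fmt(ds$data), path, row.names = FALSE)
  utils::write.csv(fmt(ds$truth), truth_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param lloq LLOQ used to re-derive the dataset object on read.
#' @export
read_cohort <- function(path, truth_path = NULL, lloq = 1.0) {
  if (is.null(truth_path)) truth_path <- sub("\\.csv$", "_truth.csv", path)
  dat <- utils::read.csv(path)
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  dat$blq <- as.logical(dat$blq)
  regimen <- dose_regimen(dose = dat$dose_mg[1], tinf = dat$tinf_h[1],
                          tau = dat$tau_h[1], n_doses = Inf)
  structure(list(data = dat, truth = truth, regimen = regimen, lloq = lloq,
                 design = sort(unique(dat$time_h))),
            class = "cohort_dataset")
}
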