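---
title: "Methods: piperacillin population PK simulation and target attainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piperacillin population PK simulation and target attainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pippk)
```

# Scope

`pippk` simulates unbound piperacillin exposure under intermittent
intravenous dosing in critically ill patients, evaluates fT>MIC-based
probability of target attainment (PTA) and cumulative fraction of response
(CFR), generates virtual study cohorts, and recovers the population
parameters from simulated concentration data. This vignette is the
package's account of the underlying science and of every numerical and
design decision a reviewer might want to audit.

# Structural model

Unbound piperacillin disposition is a two-compartment linear model with
zero-order input. With clearance CL, central and peripheral volumes Vc and
Vp, and intercompartmental clearance Q (units: L, h, L/h, mg, mg/L
throughout), the micro rate constants are k10 = CL/Vc, k12 = Q/Vc,
k21 = Q/Vp, and the hybrid exponents α ≥ β are the roots of
s² − (k10+k12+k21)s + k10·k21 = 0. All profiles are evaluated in closed
form via the "infinite infusion" decomposition: a finite zero-order input
of duration T equals an infusion switched on at t = 0 minus one switched on
at t = T. Steady state applies the geometric accumulation factor
1/(1 − e^{−λτ}) per exponential term. Closed-form correctness is not
assumed: `ode_reference()` integrates the amount equations piecewise with
`deSolve::lsoda` at tolerance 1e-11, and the test suite requires agreement
to better than 1e-5 relative over random parameter sets, plus the linear-PK
mass balance AUC_ss = dose/CL to 0.1%.

## The infusion lag (ALAG)

The fitted model includes an infusion-lag descriptor: drug left in the IV
line keeps entering the patient after the 20-minute pump stops. Because that
is physically an *extension* of the input rather than a delayed start, the
default (`alag_mode = "extended"`) models each dose as a single zero-order
input of duration tinf + ALAG carrying the full dose. A `"delay"` mode
(input of duration tinf starting ALAG after the dose time) is provided for
sensitivity analysis. The reported model-mean ALAG (0.8 h) is inconsistent
with its own bootstrap confidence interval (0.01–0.31 h); the package
defaults to the bootstrap mean 0.13 h and leaves the value configurable.
Which value produced the original simulations is unknowable, so neither is
treated as truth; the CFR acceptance tolerance absorbs the difference.

# Population model

Typical clearance follows the renal covariate law TVCL = θ_CL · CL_CR/100
(θ_CL = 16.3 L/h at CL_CR 100 ml/min). Between-subject variability is
exponential: parameter_i = typical · e^η with independent
η ~ N(0, ω²) on CL, Vc, Vp and ALAG; no variability was identified on Q and
none is simulated. No correlation matrix was reported, so the η are
independent, and the log-normal laws are untruncated.

Reported BSV magnitudes are percent CVs. The default mapping is ω = CV/100
(the convention by which pharmacometric software reports √ω² × 100); the
exact mapping ω = √(log(1 + CV²)) is available via
`cv_mapping = "exact"`. The two differ meaningfully only for Vp (67.6% CV:
0.676 vs 0.613). The ALAG variability row (0.3) is dimensionally
inconsistent with a percent CV and is taken directly as ω.

Observations carry combined residual error y = c(1 + ε_p) + ε_a,
ε_p ~ N(0, prop_cv²), ε_a ~ N(0, add_sd²) (defaults 0.01 and 0.3 mg/L),
truncated at zero. The standard proportional-plus-additive form is assumed;
an additive-on-log alternative was not reported and is not implemented.

# Target attainment

fT>MIC is the Lebesgue measure of {t ∈ [0, τ] : C_ss(t) > mic}/τ, computed
on a uniform 2,000-point grid per interval with every threshold crossing
refined by bisection to 1e-4 h. The steady-state profile rises during the
input phase and decays with non-negative exponential coefficients
afterwards, so crossings are few and the grid-plus-refinement measure is
accurate to ~1e-4; the tests compare it against a 200,000-point brute-force
measure. Ties count as attainment (fT>MIC exactly at the target fraction
attains it).

PTA is the fraction of `n_subjects` sampled individuals meeting the target,
computed on true (residual-error-free) concentrations — the standard
convention, and the paper-level quantity does not suggest otherwise. The
default Monte Carlo size is 10,000 per cell, giving a binomial standard
error below 0.5 percentage points; the source analysis did not state its
size. Grids default to MIC {2, 4, 8, 16, 32, 64} mg/L and CL_CR 10–300
ml/min in 10-ml/min steps. With `common_random_numbers = TRUE` (default)
the same standardised random effects are reused across cells, which makes
the surface exactly non-increasing in MIC and in CL_CR and nested across
targets — properties the test suite asserts.

CFR = 100·Σ PTA(MIC_i)·f_i against an `mic_distribution()`; adequacy is
CFR ≥ 80%. Distribution MICs are simulated directly at their own values
(no interpolation in MIC, which would introduce uncontrolled bias), and the
evaluation interval is steady state, matching a cohort sampled at a median
ninth dose; a first-dose analysis can be run through `conc_profile()`.

The shipped wild-type *P. aeruginosa* piperacillin-tazobactam snapshot is a
**synthetic stand-in**: its file name and `source` field say so. It was
constructed once from the published shape of the EUCAST wild-type
distribution (doubling dilutions, mode at 4 mg/L, wild type up to 16 mg/L,
a minority resistant tail) and was not calibrated against any output of
this package. Analyses that matter should substitute a current EUCAST
export via `read_mic_distribution()`.

# Synthetic cohorts

`generate_cohort()` emulates the study design: steady-state sampling at
predose and 20, 40, 60, 210 and 360 minutes ("sparse"), 4,000 mg
piperacillin (the piperacillin component of 4.5 g of the 8:1 combination
product) over 20 minutes every 6 h, LLOQ 1 mg/L, and CL_CR drawn from a
moment-matched log-normal with mean 122 and SD 59.2 ml/min, truncated by
rejection to [20, 350] ml/min (a physiologic range; the truncation clips
about 0.6% of the upper tail, so the realised SD is slightly below the
nominal one). The predose sample is defined as the trough at t = 0 of the
sampled interval. A "rich" 12-point design (0–6 h) exists for estimation
work, because the clinical sparse design cannot identify all disposition
parameters per subject.

BLQ policy: in descriptive summaries BLQ observations enter as LLOQ/2;
in estimation they are dropped (M1), mirroring the exclusion of
unquantifiable troughs from the observed attainment denominator. Both are
defaults of functions, not hidden constants. Quartile summaries split CL_CR
at `stats::quantile` type-7 boundaries (linear interpolation between order
statistics) so the rule is unambiguous.

What the generator does *not* emulate: demographics and severity scores,
fluid balance, vasopressors, inter-occasion variability, assay drift, or
real sampling-time jitter. Passing tests therefore demonstrate
self-consistency of model, simulator and estimator — not fidelity to any
real cohort.

# Estimation

The original analysis used FOCE-with-interaction nonlinear mixed-effects
estimation. That algorithm is deliberately **not** re-implemented. Instead a
two-stage estimator operates on richly sampled synthetic cohorts, where
individual parameters are identifiable and the estimator is auditable:

1. **Stage 1** — per subject, weighted least squares on quantifiable
   concentrations with weights 1/(prop_cv²·c² + add_sd²), minimised over
   log(CL, Vc, Vp, Q) by Levenberg–Marquardt (`minpack.lm::nls.lm`,
   ftol = ptol = 1e-12) from three deterministic jittered starts, best
   objective kept. ALAG is fixed at the population value (weakly
   identifiable from concentrations at this design). Log-parameters are
   box-bounded within a factor 10 (~3.4 BSV log-SDs) of the typical values:
   subjects drawn near the one-compartment limit leave the Vp/Q split on a
   flat objective, and without bounds such fits collapse to absurd
   magnitudes. Near-equal objectives are tie-broken toward the typical
   values for the same reason.
2. **Stage 2** — θ_CL is the geometric mean of CL_i/(CL_CR_i/100) (the
   covariate law solved for its coefficient); other fixed effects are
   geometric means; ω are SDs of the individual log-deviations; residual
   error comes from a moment fit of e² against prediction².

The renal covariate is tested by a nested Gaussian likelihood ratio on the
individual clearance estimates: log CL_i = a + γ·log(CL_CR_i/100) with the
exponent γ estimated (full) against γ = 0 (reduced), statistic
n·log(RSS_red/RSS_full), threshold qchisq(0.95, 1) = 3.84. A fixed-γ = 1
proportional model would not nest the constant model (equal parameter
counts, possibly negative statistic, zero size under the null), so the
estimated-exponent form is the correct nested analogue; the generating law
γ = 1 lies inside the full model. The Pearson correlation between CL_i and
CL_CR_i is reported alongside.

Uncertainty comes from a nonparametric bootstrap: subjects are resampled
with replacement and stage 2 is recomputed per replicate (stage-1 fits are
subject-specific and therefore reusable), with 2.5/97.5 empirical
percentiles. The default replicate count is 1,000.

Known limitation: even with bounds and tie-breaking, individual Vp
estimates remain noisy for extreme variability draws (ω_Vp = 0.676 makes
near-one-compartment subjects common), so θ_Vp recovery carries more
variance than the other fixed effects. This is a property of the two-stage
estimator at these study conditions, not an optimizer artefact; the test
suite documents it.

# Reproducibility and problem sizes

Every stochastic function accepts a `seed`; pipeline stages derive distinct
sub-seeds from one master seed via `derive_seed()` so stage order cannot
change results. Command outputs are written at 6 significant digits so
repeated runs are byte-identical (`raw = TRUE` for full precision).

Sizes used by the test suite and acceptance script, chosen as the package's
own balance of Monte Carlo error against turnaround: 10,000 subjects per
PTA/CFR cell (binomial SE < 0.5 pp), 1,000-subject cohorts for attainment
fractions, 60-subject rich cohorts for recovery, 200–1,000 bootstrap
replicates, 200 replicates for the covariate-test size and power studies,
and 100 random parameter sets for the closed-form-versus-ODE property.
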