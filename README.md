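# pippk

Population-pharmacokinetic simulation of piperacillin target attainment in
critically ill patients with sepsis, focused on one clinical question: when
renal function is *augmented* rather than impaired, does standard
intermittent dosing (4.5 g piperacillin-tazobactam IV over 20 minutes every
6 hours, i.e. 4,000 mg piperacillin) still keep unbound drug concentrations
above the pathogen's MIC for long enough?

The package is written for pharmacometricians and infectious-disease
researchers who want a fully scripted, testable version of this analysis:
simulation of virtual patient cohorts, probability of target attainment
(PTA) surfaces, cumulative fraction of response (CFR) against wild-type MIC
distributions, and recovery of the population parameters from simulated
concentration data.

## The model

Unbound piperacillin follows a two-compartment linear model with zero-order
(infusion) input, solved in closed form (micro constants
k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp; hybrid exponents α ≥ β from
s² − (k10+k12+k21)s + k10·k21 = 0), with multiple-dose superposition and a
geometric-series steady state. An infusion lag ALAG (residual drug flushed
through the IV line after pump stop) extends the zero-order input.

The population model is

* TVCL = θ_CL · CL_CR / 100 — typical clearance proportional to measured
  creatinine clearance normalised to 100 ml/min (the renal covariate law);
* exponential between-subject variability, P_i = TV · e^η, η ~ N(0, ω²),
  on CL, Vc, Vp and ALAG (none on Q);
* combined residual error y = c·(1 + ε_p) + ε_a.

Defaults are the final-model estimates: θ_CL 16.3 L/h (at CL_CR 100),
Vc 19.9 L, Vp 18.8 L, Q 37.3 L/h; BSV 56.0 / 29.6 / 67.6 %CV on CL / Vc /
Vp, ω 0.3 on ALAG; residual error 1.0 %CV + 0.3 mg/L SD.

The pharmacodynamic index is fT>MIC, the fraction of the dosing interval
with unbound concentration above the MIC; targets of 50% and 100% are
evaluated. PTA(MIC, CL_CR) is the Monte Carlo fraction of simulated subjects
meeting the target; CFR = Σ_i PTA(MIC_i)·f_i weights PTA by a pathogen MIC
frequency distribution, with dosing considered adequate at CFR ≥ 80%.

## Worked example

```r
library(pippk)
pop <- population_params()     # final-model parameters
reg <- standard_regimen()      # 4,000 mg over 20 min q6h, steady state

## one simulated subject with augmented renal clearance (CL_CR 180 ml/min)
p <- sample_individual(pop, clcr = 180)
round(conc_steady_state(p, reg, c(0, 1/3, 1, 3, 6)), 2)
#> [1]  3.18 86.77 51.48 15.60  3.18

## PTA for 50% fT>MIC at the susceptibility breakpoint (MIC 16 mg/L)
pta(pop, reg, clcr = 180, mic = 16, target = 0.5, n_subjects = 5000, seed = 42)
#> [1] 0.388

## CFR against the shipped wild-type P. aeruginosa snapshot
cfr_table(pop, reg, clcr_values = c(60, 120, 180), dist = eucast_pa_piptaz(),
          targets = c(0.5, 1), n_subjects = 5000, seed = 42)
#>   clcr_ml_min target_fraction cfr_pct adequate    n seed
#> 1          60             0.5    85.7     TRUE 5000   42
#> 2         120             0.5    71.9    FALSE 5000   42
#> 3         180             0.5    57.2    FALSE 5000   42
#> 4          60             1.0    74.1    FALSE 5000   42
#> 5         120             1.0    44.8    FALSE 5000   42
#> 6         180             1.0    25.9    FALSE 5000   42

## a virtual 47-patient study cohort: how many keep their steady-state
## trough above 16 mg/L (100% fT>MIC)?
ds <- generate_cohort(47, sampling_design("sparse"), pop, seed = 42)
trough_attainment(ds, mic = 16)
#> $count:    16
#> $n:        47
#> $fraction: 0.34
```

Reading: with normal-to-augmented renal clearance the 50% fT>MIC CFR drops
below the 80% adequacy line somewhere between CL_CR 60 and 120 ml/min, and
only about a third of a typical study cohort sustains a trough above
16 mg/L — standard intermittent dosing is unlikely to cover less susceptible
pathogens once clearance is augmented.

Estimation tools (`two_stage_fit()`, `bootstrap_ci()`, `covariate_lrt()`,
`gof_diagnostics()`) recover the generating population from richly sampled
cohorts; `cmd_pta()` / `cmd_cfr()` / `cmd_cohort()` / `cmd_fit()` plus the
wrapper in `inst/scripts/pippk-cli.R` run the same stages from a JSON run
configuration with deterministic, seed-stamped CSV/JSON outputs.

The shipped MIC snapshot (`inst/extdata/eucast_paeruginosa_piptaz_synthetic.tsv`)
is a synthetic EUCAST-style stand-in for the wild-type *P. aeruginosa*
piperacillin-tazobactam distribution (see its `source` line); substitute a
current EUCAST export via `read_mic_distribution()` for real analyses.

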