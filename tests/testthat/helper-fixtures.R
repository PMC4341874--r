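# Shared fixtures: the final-model population, the study regimen and small
# helpers used across test files. Everything is built in code.

table2_pop <- function(...) population_params(...)

table2_params <- function(clcr = 100) {
  pk_params(cl = 16.3 * clcr / 100, vc = 19.9, vp = 18.8, q = 37.3, alag = 0.13)
}

study_regimen <- function() standard_regimen()

# population with all randomness switched off (deterministic typical subject)
degenerate_pop <- function(...) {
  population_params(bsv_cv = c(cl = 0, vc = 0, vp = 0, alag = 0),
                    ruv_prop_cv = 0, ruv_add_sd = 0, ...)
}

# random valid parameter sets for property-style comparisons
random_pk_params <- function(n) {
  lapply(seq_len(n), function(i) {
    pk_params(cl = exp(stats::runif(1, log(2), log(60))),
              vc = exp(stats::runif(1, log(5), log(60))),
              vp = exp(stats::runif(1, log(5), log(60))),
              q = exp(stats::runif(1, log(5), log(80))),
              alag = stats::runif(1, 0, 0.3))
  })
}

local_seed <- function(seed, env = parent.frame()) {
  withr::local_preserve_seed(.local_envir = env)
  set.seed(seed)
}
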