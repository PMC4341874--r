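{
  "population": {
    "theta_cl": 16.3,
    "theta_vc": 19.9,
    "theta_vp": 18.8,
    "theta_q": 37.3,
    "theta_alag": 0.13,
    "bsv_cv": {
      "cl": 56,
      "vc": 29.6,
      "vp": 67.6,
      "alag": 0.3
    },
    "ruv_prop_cv": 0.01,
    "ruv_add_sd": 0.3,
    "covariate": "clcr_linear",
    "cv_mapping": "approx"
  },
  "regimen": {
    "dose_mg": 4000,
    "tinf_h": 0.333333333333333,
    "tau_h": 6
  },
  "grid": {
    "mic": [2, 4, 8, 16, 32, 64],
    "clcr": {
      "from": 10,
      "to": 300,
      "by": 10
    },
    "targets": [0.5, 1]
  },
  "simulation": {
    "n_subjects": 10000,
    "seed": 20150130,
    "common_random_numbers": true,
    "alag_mode": "extended"
  },
  "cohort": {
    "n": 48,
    "design": "sparse",
    "clcr": {
      "mean": 122,
      "sd": 59.2,
      "lower": 20,
      "upper": 350
    },
    "lloq": 1
  },
  "fit": {
    "n_boot": 1000,
    "min_converged": 10
  }
}
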