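{
  "scenario": {
    "clades": [
      {"name": "bacteria", "n_lineages": 60, "covariate_rho": 0.3},
      {"name": "archaea", "n_lineages": 19, "covariate_rho": -0.8}
    ],
    "n_genes": 80,
    "residual_sd": 0.3,
    "missing_fraction": 0.2,
    "outlier_fraction": 0.005,
    "outlier_shift": 3
  },
  "min_mutations": 32,
  "min_fraction": 0.7,
  "tol": 1e-06,
  "max_iter": 1000,
  "outlier_alpha": 0.05,
  "min_tips": 20,
  "min_depth": 0.2,
  "bca_bootstrap": 1000,
  "subsample_draws": 10000,
  "subsample_n": 19,
  "seed": 1
}
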