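{
  "seed": 42,
  "log_level": "warn",
  "paths": {"output_dir": "smoke_out"},
  "simulate": {
    "n": 200,
    "m": 500,
    "maf_range": [0.05, 0.5],
    "missing_rate": 0.02,
    "architecture": {"kind": "polygenic", "h2": 0.5}
  },
  "qc": {
    "min_call_rate": 0.9,
    "min_maf": 0.05,
    "hwe_p_floor": 1e-05,
    "max_sample_missing": 0.1
  },
  "adjust": {
    "factors": ["sex", "birth_year"],
    "covariates": ["fatten_days", "init_weight"]
  },
  "methods": {
    "gblup": {"method": "gblup"},
    "en_0.001": {"method": "en", "alpha": 0.001, "n_lambda": 50}
  },
  "validation": {"scheme": "kfold", "k": 3}
}
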