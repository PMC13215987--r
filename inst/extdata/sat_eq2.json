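{
  "response": "sat_manual_cm2",
  "terms": {
    "(Intercept)": 0.67,
    "sat_otsu_cm2": 1.037,
    "age_category": 3.337
  },
  "weighting": "inverse_sex_age_frequency",
  "note": "Published SAT bias correction: manual-reference SAT regressed on automated (Otsu) SAT and adult age category (child = reference). Cohort- and protocol-specific; refit before use on other acquisition settings."
}
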