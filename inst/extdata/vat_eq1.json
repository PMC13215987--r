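{
  "response": "vat_manual_cm2",
  "terms": {
    "(Intercept)": 7.224,
    "vat_otsu_cm2": 1.112,
    "obesity": 7.583
  },
  "weighting": "inverse_sex_age_frequency",
  "note": "Published VAT bias correction: manual-reference VAT regressed on automated (Otsu) VAT and obesity status. Cohort- and protocol-specific; refit before use on other acquisition settings."
}
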