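{
 "table": "table81",
 "kind": "lms",
 "parameter_id": "aorta_pwv",
 "covariate": "age_years",
 "units": "m/s",
 "precision": 2,
 "title": "Aortic pulse wave velocity in children: LMS parameters by age",
 "citation": "compilation table 81 (pediatric aortic stiffness LMS by age)",
 "notes": [
  "The source prints LMS parameters only; no centile columns.",
  "The age column is in whole years; the under-one-year row is stored as age 0."
 ]
}
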