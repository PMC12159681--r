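{
 "table": "table80",
 "kind": "lms",
 "parameter_id": "aorta_dist_asc",
 "covariate": "age_years",
 "units": "10^-3 mmHg^-1",
 "precision": 2,
 "title": "Ascending aortic distensibility in children: LMS parameters by age",
 "citation": "compilation table 80 (pediatric aortic stiffness LMS by age)",
 "notes": [
  "The source prints LMS parameters only; no centile columns.",
  "The age column is in whole years; the under-one-year row is stored as age 0."
 ]
}
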