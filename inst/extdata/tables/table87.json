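{
 "table": "table87",
 "kind": "regression",
 "parameter_id": "pa_area_mpa",
 "title": "Predicted main pulmonary artery area in children (phase-contrast cine)",
 "citation": "compilation table 87 (pediatric main pulmonary artery area by BSA)",
 "formula": "predicted = intercept + slope * BSA",
 "notes": [
  "The source prints no residual SD; only a predicted value (no z-score) is available."
 ]
}
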