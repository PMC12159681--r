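{
 "table": "table86",
 "kind": "regression",
 "parameter_id": "pa_diam",
 "title": "Predicted pulmonary artery diameters in children (contrast-enhanced MRA)",
 "citation": "compilation table 86 (pediatric pulmonary arteries, predicted diameter by sqrt(BSA))",
 "formula": "predicted = intercept + slope * BSA^0.5; z = (measured - predicted)/SD of residuals",
 "notes": []
}
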