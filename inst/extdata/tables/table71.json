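{
 "table": "table71",
 "kind": "regression",
 "parameter_id": "aorta_diam",
 "title": "Predicted thoracic aortic diameters in children (contrast-enhanced 3D MRA)",
 "citation": "compilation table 71 (pediatric thoracic aorta, predicted diameter by sqrt(BSA))",
 "formula": "predicted = intercept + slope * BSA^0.5; z = (measured - predicted)/SD of residuals",
 "notes": []
}
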