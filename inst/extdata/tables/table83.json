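{
 "table": "table83",
 "kind": "ranges",
 "title": "Main pulmonary artery dimensions and distension in adults, all ages combined",
 "citation": "compilation table 83 (pulmonary artery, adults, cross-sectional bSSFP)",
 "notes": [
  "Only the all-ages rows are packaged; decade strata are in the source compilation."
 ]
}
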