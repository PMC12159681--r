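{
 "table": "table92",
 "kind": "ranges",
 "title": "Native myocardial T1 relaxation time (ms) in children, mid-septal ROI",
 "citation": "compilation table 92 (pediatric native T1 by field strength, vendor and sequence)",
 "notes": [
  "T1 is strongly sequence- and vendor-specific; the group field must be matched explicitly."
 ]
}
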