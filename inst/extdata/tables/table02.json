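{
 "table": "table02",
 "kind": "ranges",
 "title": "LV volume, mass and function in adult men and women (bSSFP, papillary muscles in LV mass)",
 "citation": "compilation table 2 (adult LV, bSSFP, papillary muscles in mass)",
 "units_by_parameter": true,
 "notes": [
  "Pooled random-effects estimates across the cited source cohorts.",
  "The female cardiac index row is a median with interquartile limits and is excluded from z-score computation."
 ]
}
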