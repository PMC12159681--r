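{
 "table": "table41",
 "kind": "ranges",
 "title": "LV volume, mass and function in adult athletes (papillary muscles in LV volume)",
 "citation": "compilation table 41 (adult athletes, bSSFP)",
 "notes": [
  "Single-study ranges: mean plus/minus twice the SD, rounded to integer."
 ]
}
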