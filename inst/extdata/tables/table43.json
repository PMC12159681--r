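{
 "table": "table43",
 "kind": "ranges",
 "title": "RV volume, mass and function in adult athletes (papillary muscles in RV volume)",
 "citation": "compilation table 43 (adult athletes, bSSFP)",
 "notes": [
  "Single-study ranges: mean plus/minus twice the SD, rounded to integer."
 ]
}
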