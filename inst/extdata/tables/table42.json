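{
 "table": "table42",
 "kind": "ranges",
 "title": "Indexed LV parameters in adult elite athletes (papillary muscles in LV mass)",
 "citation": "compilation table 42 (adult elite athletes, bSSFP, >18 training hours/week)",
 "notes": [
  "Single-study ranges: mean plus/minus twice the SD, rounded to integer."
 ]
}
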