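{
 "table": "table37",
 "kind": "centiles",
 "title": "Centiles of maximal LA volume (mL) by BSA in boys (biplane area-length)",
 "citation": "compilation table 37 (pediatric maximal LA volume by BSA, boys)",
 "covariate": "bsa_m2",
 "units": "mL",
 "notes": [
  "The source provides boys only."
 ]
}
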