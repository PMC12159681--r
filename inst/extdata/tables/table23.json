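{
 "table": "table23",
 "kind": "centiles",
 "title": "Centiles of LV volumes (mL) by body height in boys (papillary muscles excluded from volume)",
 "citation": "compilation table 23 (pediatric LV volumes by height, boys)",
 "covariate": "height_cm",
 "units": "mL",
 "notes": []
}
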