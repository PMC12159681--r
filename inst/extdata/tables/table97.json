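{
 "table": "table97",
 "kind": "ranges",
 "title": "Myocardial T2 relaxation time (ms) in children, mid-septal ROI",
 "citation": "compilation table 97 (pediatric T2 by field strength, vendor and sequence)",
 "notes": []
}
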