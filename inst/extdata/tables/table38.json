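{
 "table": "table38",
 "kind": "lms",
 "parameter_id": "ra_maxvol_bsa",
 "covariate": "age_years",
 "units": "mL/m^2",
 "precision": 0,
 "title": "Maximal RA volume indexed to BSA in children: LMS parameters and centiles by age",
 "citation": "compilation table 38 (pediatric atrial volume LMS by age)",
 "extreme_centile_convention": "z = +/-2 for the 3rd and 97th centiles",
 "centile_audit": {
  "male": {
   "within_1_unit": "49/105"
  },
  "female": {
   "within_1_unit": "105/105"
  }
 },
 "notes": [
  "Panels whose printed centile columns do not agree with their own printed L/M/S parameters (transcribed verbatim from the source compilation) are flagged centiles_consistent = FALSE and excluded from bulk reproduction checks; the discrepancy is a property of the source tables, not of the transcription."
 ]
}
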