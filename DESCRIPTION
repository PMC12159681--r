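Package: cmrref
Title: Reference Ranges, Z-Scores and Derived Quantities for Quantitative
    Cardiovascular Magnetic Resonance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying normative reference values for
    quantitative cardiovascular magnetic resonance (CMR). Implements
    single-study mean +/- 2 SD reference ranges, DerSimonian-Laird
    random-effects pooling of study-level aggregates with frequentist 95%
    reference-range estimation, evaluation of pediatric LMS growth models and
    regression-based z-scores from packaged parameter tables, lookup in
    centile-by-height and centile-by-BSA tables, and the clinical formula
    toolkit used by normative CMR compilations: body surface area indexing,
    area-length atrial volumes, sphericity index, aortic distensibility,
    pulse-wave velocity with foot-to-foot transit-time estimation,
    extracellular volume fraction, T2*-derived iron metrics and grading,
    valve and diastolic-function staging, and box-counting fractal dimension
    of trabeculation masks. Ships a machine-readable store of transcribed
    normative tables and a classification API that maps individual
    measurements to a status, z-score and centile, plus seeded synthetic-data
    generators that emulate the statistical structure of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    png,
    optparse
Config/testthat/edition: 3
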