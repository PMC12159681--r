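# cmrref

Normative reference values ("normal values") for quantitative cardiovascular
magnetic resonance (CMR), as an R package.

Quantitative CMR — chamber volumes and mass, ejection fraction, vessel
dimensions, T1/T2/T2\* relaxation times, flow and stiffness indices — is only
interpretable against reference ranges from healthy cohorts. Those ranges are
published as aggregates: per-study (n, mean, SD) triples, pooled tables,
pediatric LMS grids, regression fits and centile tables. `cmrref` is for
imagers, clinical researchers and core-lab statisticians who need to

* **build** reference ranges from study-level aggregates,
* **evaluate** pediatric z-scores and centiles from published parameter
  tables, and
* **classify** individual measurements against a machine-readable store of
  transcribed normative tables.

## The statistics at the core

Single-study ranges use the field's mean ± 2 SD convention, with limits
rounded half away from zero at the printed precision. Multiple studies of the
same parameter are combined under a random-effects model,
θᵢ ~ N(μ, τ²), with τ² estimated by the DerSimonian–Laird moment estimator
(truncated at zero) and the pooled mean by inverse-variance weights
wᵢ\* = 1/(sᵢ²/nᵢ + τ̂²). The 95% reference range is then the frequentist
estimate of the 0.025/0.975 population quantiles around that model,

    μ̂ ± z₀.₉₇₅ · √(σ̂² + τ̂²),

where σ̂² is the pooled within-study variance (a t-quantile variant that also
propagates the standard error of μ̂ is available). Pediatric z-scores use the
LMS transform z = [(X/M)ᴸ − 1]/(L·S) with linear interpolation of L, M, S
over the covariate grid, or published allometric fits
z = (measured − predicted)/SD of residuals. A clinical formula toolkit covers
BSA indexing, area-length atrial volumes, sphericity, aortic distensibility,
foot-to-foot pulse wave velocity, ECV, T2\*-iron metrics and grading, valve
and diastolic staging, and box-counting fractal dimension of trabeculation
masks. Seeded generators simulate study aggregates, LMS populations, flow
waveform pairs and fractal reference images for testing the whole pipeline.

## Worked example

```r
library(cmrref)

# five studies reporting LV end-diastolic volume in healthy men
studies <- data.frame(
  study_id = paste0("s", 1:5), parameter_id = "lvedv",
  n = c(120, 85, 240, 60, 400),
  mean = c(146, 152, 148, 139, 150),
  sd = c(30, 35, 32, 28, 31))

est <- pool_random_effects(studies)
est
#> Pooled estimate over 5 studies (n = 905):
#>   mu = 147.4 (se 1.75), tau2 = 8.384, within-study sd = 31.35

frequentist_reference_range(est, decimals = 0)
#> Reference range [pooled_frequentist]: 86 - 209  (mean 147.432, sd 31.4815)
```

The pooled mean is 147.4 mL; the between-study variance τ̂² = 8.4 mL² widens
the population SD from 31.35 to 31.48 mL, and the estimated central-95%
range for an individual healthy man is 86–209 mL after integer rounding.

```r
reg <- load_registry()

# adult man with LVEF 50%: below the packaged adult range 53-79%
classify(measurement_record("lvef", 50, sex = "male", age = 50), reg)
#> Classification: below_range, z = -2.29  [compilation table 2 (adult LV, bSSFP, papillary muscles in mass)]

# 6-year-old boy, BSA-indexed maximal LA volume 52 mL/m2: LMS z-score
classify(measurement_record("la_maxvol_bsa", 52, sex = "male", age = 6), reg)
#> Classification: within_range, z = 1.70, centile = 95.5  [compilation table 36 (pediatric atrial volume LMS by age)]

grade_iron(15, "1.5T")
#> [1] overload

# pulse wave velocity from a simulated noisy waveform pair (truth: 8 m/s)
pair <- gen_flow_pair(true_pwv = 8, delta_x = 0.4, dt = 4,
                      noise_sd = 0.05, seed = 2)
round(pwv(pair)$pwv_ms, 2)
#> [1] 8.22
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/cmrref` (subcommands `pool`, `classify`, `zscore`, `derive`,
`pwv`, `simulate`, `tables`).

The packaged table store lives in `inst/extdata/tables/` (one CSV per source
table plus a JSON sidecar with citation, kind and units);
`verify_tables()` re-derives every packaged single-study range from its mean
and SD and re-computes LMS centile cells against their printed values. See
the methods vignette (`vignettes/cmr-reference-ranges.Rmd`) for the model,
conventions (rounding, limit inclusivity, the z = ±2 extreme-centile
convention) and a documented inconsistency in two source LMS panels.

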