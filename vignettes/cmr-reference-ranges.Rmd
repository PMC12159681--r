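---
title: "Methods: reference ranges, growth models and derived quantities for quantitative CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference ranges, growth models and derived quantities for quantitative CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrref)
```

Quantitative cardiovascular magnetic resonance (CMR) produces continuous
measurements — chamber volumes and mass, ejection fraction, vessel
dimensions, relaxation times, flow-derived stiffness indices — whose clinical
interpretation requires normative reference ranges. Normative compilations
aggregate many healthy-cohort studies, but publish only study-level summary
statistics (n, mean, SD) and parameter tables, never individual data. This
package implements the full methodology for building reference ranges from
such aggregates and for classifying individual patients against them.

## The reference-range model

### Single-study ranges

For one study reporting mean $m$ and standard deviation $s$ for a normally
distributed parameter, the central 95% reference interval is approximated by

$$ [\,m - 2s,\; m + 2s\,], $$

the field's long-standing convention (the exact normal multiplier would be
1.96; published tables use 2). `mean_sd_range()` implements this, including
the degenerate $s = 0$ case. Ranges from studies with fewer than 40 subjects
are statistically unreliable; `eligibility_filter()` encodes that inclusion
rule (40 per sex when sex-specific ranges are needed).

### Pooling study aggregates

When $k$ studies measure the same parameter with the same technique, their
means are combined under the random-effects model: study $i$'s true mean
$\theta_i \sim N(\mu, \tau^2)$ and its observed mean has sampling variance
$v_i = s_i^2 / n_i$. `pool_random_effects()` estimates $\tau^2$ by the
DerSimonian–Laird moment estimator truncated at zero,

$$ \hat\tau^2 = \max\!\left(0,\;
   \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),
   \qquad w_i = 1/v_i, $$

and the pooled mean by inverse-variance weights $w_i^* = 1/(v_i +
\hat\tau^2)$. The pooled *within-study* variance is the sample-size-weighted
average $\hat\sigma^2 = \sum (n_i - 1) s_i^2 / \sum (n_i - 1)$. Any study
with $n_i < 2$ is rejected (its mean's variance is undefined).

### Frequentist reference range from aggregated data

The 0.025/0.975 population quantiles are estimated around the random-effects
model as

$$ \hat\mu \;\pm\; z_{0.975}\,\sqrt{\hat\sigma^2 + \hat\tau^2}, $$

i.e. the spread of an individual drawn from a random study combines the
within-study and between-study components. This normal-approximation variant
is the default because it is internally consistent with the published pooled
tables (a pooled LVEDV row of 147, SD 33 prints limits 83–211 ≈ 147 ±
1.96·33). A t-quantile variant that additionally propagates the pooled
mean's standard error ($t_{k-1}\sqrt{\hat\sigma^2 + \hat\tau^2 +
\widehat{se}^2_\mu}$) is available through `variant = "t"`; with few studies
it is wider and more conservative. Whether the published tables' pooled SD
column is $\sqrt{\hat\sigma^2 + \hat\tau^2}$ or a sample-size-weighted SD is
not documented at the source; this package reports
$\sqrt{\hat\sigma^2+\hat\tau^2}$ in the range object and keeps both variants
selectable.

### Rounding

Printed limits carry no more digits than CMR can measure. "Rounding up" in
the sources' wording means rounding *to the printed precision*, half away
from zero — a published pulmonary-artery row with mean 27.4, SD 2.6 prints
22–33, i.e. 22.2 → 22 (so not ceiling semantics) and 32.6 → 33.
`round_half_away()` and `round_limits()` implement exactly this and are
idempotent.

```{r}
r <- mean_sd_range(27.4, 2.6, decimals = 0)
c(r$lower, r$upper)
```

## Pediatric growth models

### LMS z-scores

Pediatric parameters change with body size, so childhood tables publish LMS
parameters per age (or height/BSA) grid point: L the Box–Cox skewness power,
M the median, S the coefficient of variation. A measurement $x$ maps to

$$ z = \frac{(x/M)^L - 1}{L\,S}, \qquad
   x = M\,(1 + L S z)^{1/L}, $$

with the continuous log-limit used for $|L| < 10^{-7}$. Between grid points,
L, M and S are interpolated linearly per component — the sources say only
"interpolated", and linear interpolation is exact at the published points
and monotone between them. No extrapolation is allowed: a growth model is
invalid outside its fitted range, so out-of-grid covariates raise an error
(and classify to `no_reference` in batch mode).

Two conventions matter when reproducing printed centile columns:

* the published tables equate the 3rd/97th centiles with $z = \mp 2$ (not
  the exact quantile $\mp 1.8808$); `lms_centile()` honors that by default
  (`extreme_z2 = TRUE`) because it is what reproduces the printed cells;
* reproduced cells are rounded half away from zero at the table's printed
  precision.

The transform has a feasibility bound $1 + LSz > 0$; for the packaged boys'
atrial-volume parameters this cuts the lower tail at $z \approx -2.76$, so
about 0.3% of standard-normal draws are infeasible. The synthetic sampler
(`gen_lms_population()`) rejects and redraws these and reports the count.

### The source inconsistency in the atrial LMS tables

Transcription of the pediatric atrial-volume tables surfaced an internal
inconsistency in the source compilation: in the maximal-LA-volume table the
*girls'* printed L/M/S columns contradict the girls' own printed centile
columns (by up to tens of mL/m² at the 97th centile), while the boys' panel
reproduces all 105 printed cells within one unit; in the maximal-RA-volume
table the situation is mirrored (boys inconsistent, girls consistent). The
inconsistent panels' parameter columns show fingerprints of a production
error (an exactly arithmetic L sequence; an M outlier breaking an otherwise
smooth trend). The package ships both panels verbatim — transcription
fidelity first — with a per-row `centiles_consistent` flag recorded from a
pre-packaging audit. Bulk reproduction checks run over the consistent
panels; a dedicated regression test pins the measured disagreement of the
flagged panels so the defect stays visible rather than silently "fixed".
Z-scores computed from the flagged panels inherit the source's defect and
should be interpreted with caution.

Even in the self-consistent panels, only about 80–84% of printed cells
reproduce *exactly*: the sources round L, M and S to three decimals, which
moves roughly one cell in six across an integer-rounding boundary. All cells
reproduce within one unit, which is the tolerance the package's checks
enforce.

### Regression z-scores and centile tables

Pediatric vessel dimensions are normalized through published allometric
fits, `predicted = a + b·BSA^0.5` (or `a + b·BSA`), with
`z = (measured − predicted) / SD of residuals` (`regression_z()`). One
packaged table prints no residual SD and therefore yields predictions only.
Printed centile-by-height and centile-by-BSA tables are looked up by linear
interpolation across the covariate, with the measurement bracketed between
adjacent centile columns (`centile_band()`); the approximate continuous
centile interpolates linearly on the centile scale within the bracketing
pair, which is a display aid, not a distributional claim.

## Classification and the table store

The table store is one CSV per source table plus a JSON sidecar (citation,
kind, units, stratum schema) — auditable line by line against the source.
`select_reference()` routes a measurement to the most specific applicable
entry with precedence sex+age+ethnicity over sex+age over sex over
unstratified; matched field strength, and an explicitly selected
cohort/technique group, are more specific still. Two deliberate choices:

* rows tagged with a cohort or technique group (athlete class,
  vendor/sequence) are only eligible when the caller selects that group —
  an athlete range must never capture a general patient by accident;
* printed age bands ("20–29") are implemented half-open, $[20, 30)$, so
  adjacent decade bands tile the age axis without gaps.

Remaining equal-specificity ties across model kinds prefer distributional
models (LMS, then regression, then centile table, then plain range), since
they use more of the covariate information; ties *within* a kind are a
configuration error naming both rows. The sources do not state whether
printed limits are inclusive; this package treats values equal to a limit as
within range, a documented convention. Median/IQR rows (skewed parameters)
classify by their printed limits but carry no z-score.

## Derived-quantity formulas

The clinical toolkit implements the standard formulas the normative tables
presuppose, each a pure function with guarded domains: DuBois (default) and
Mosteller BSA; BSA indexing; biplane/monoplane area-length atrial volumes
(ellipsoid constant $8/3\pi$, shortest-length rule for the pediatric
convention, plus the empirically calibrated 0.848 variant, which differs
from the ellipsoid mean-length variant by 0.1%); LV sphericity
(volume over the sphere of the 4-chamber length); aortic distensibility
$(A_{max}-A_{min})/(A_{min}\,\Delta P)$ in $10^{-3}\,\mathrm{mmHg}^{-1}$;
ECV from pre/post-contrast T1 and hematocrit; synthetic hematocrit from
native blood T1 (site calibration required — none is shipped, since the
calibration is scanner- and sequence-specific); $R2^* = 1000/T2^*$; iron
concentration $45 \cdot T2^{*-1.22}$ mg/g; iron-load grading (thresholds
20/10 ms at 1.5T, 12/5.5 ms at 3T, boundaries assigned to the milder class
so the grades partition $(0,\infty)$); aortic-stenosis staging
(worst-criterion-wins across velocity and orifice area); and
diastolic-function classification, which returns the *set* of consistent
classes because normal and pseudonormal filling are not separable on MDT
and E/A alone.

### Pulse wave velocity

$\mathrm{PWV} = \Delta x / \Delta t$ with $\Delta x$ the centerline path
length and $\Delta t$ the foot-to-foot transit time. The foot of each
waveform is the intersection of (a) the pre-systolic baseline, estimated as
the median of pre-peak samples below 10% normalized amplitude — the sources
say "constant horizontal diastolic flow" without an estimator, so a robust
location estimate is used — and (b) a least-squares line through the rising
limb samples with normalized amplitude in [0.20, 0.80] (the earliest
contiguous run, if the band is interrupted by noise). The alternative
midpoint method takes the linearly interpolated 50%-amplitude time.
Identical feet make $\Delta t$ exactly zero; a non-positive $\Delta t$ is
flagged by `transit_time()` and is an error in `pwv()`.

### Box-counting fractal dimension

Trabeculation complexity is quantified as the negative slope of
$\log N(s)$ vs $\log s$, where $N(s)$ counts occupied boxes of edge $s$ on a
fixed-origin grid. Defaults are dyadic sizes from 2 px to a quarter of the
image side; the sources specify neither sizes nor origin handling, so both
are fixed and documented. For area-like sets (a filled region) the
asymptotic slope 2 only emerges when boxes are small relative to the
feature, so validation against a filled square uses sizes 2–16 px; curves
(Koch, boundaries) are well estimated at the defaults. Per-slice values are
summarized by `fd_summarize()`: global = mean over slices, maximal apical =
maximum over the apical half of the stack.

## What the synthetic generators emulate — and what they do not

* `gen_study_aggregates()` reproduces exactly the two-level normal model the
  pooling assumes (study means around $\mu$ with SD $\tau$, individuals
  around the study mean with SD $\sigma$). Real study aggregates add
  technique heterogeneity, unequal and non-random sample sizes, rounding of
  published means/SDs, and non-normal parameters — so passing recovery tests
  validates the estimator under its own assumptions, not robustness to
  model violation.
* `gen_lms_population()` inverts the LMS transform on standard-normal draws,
  so sampled values have exactly the intended z-scores; real pediatric data
  add measurement error and cohort effects the LMS fit has averaged out.
* `gen_flow_pair()` delays a smooth systolic template (80 ms half-sine
  upstroke, 300 ms decay, 1000 ms cycle — physiologically plausible shape
  constants that recovery tests do not depend on) and optionally applies
  multiplicative Gaussian noise. Real phase-contrast waveforms add reflected
  waves, baseline drift and velocity aliasing.
* `gen_fractal_image()` rasterizes shapes of known dimension (line, Koch
  curve, square boundary, filled square) to validate the box counter against
  analytic truth; it does not simulate myocardial anatomy.

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state.

## Problem sizes and numerical choices

The bundled checks run at desk scale, chosen to keep the full suite fast
while leaving Monte-Carlo margins comfortable: coverage of the pooled
reference range uses 500 replicates of K = 10 studies × n = 200 (mean
population fraction below the upper limit checked against 0.975 ± 0.02);
estimator recovery uses 200 replicates of K = 50 × n = 500; the LMS
uniformity check uses 10⁴ draws; Koch validation uses a 729-px raster at 6
iterations (729 = 3⁶ aligns the raster with the curve's thirds). Numerical
tolerances: the DL implementation must match an independently coded oracle
to 10⁻¹⁰; LMS round-trips to 10⁻⁹; tie-breaks and boundary conventions are
as documented above. Degenerate inputs (zero SD, flat waveforms, empty
masks, infeasible LMS inversions) raise typed domain errors rather than
propagating NaN.

## Known limitations

* The table store is a representative subset of the source compilation
  (adult LV/athlete/pulmonary-artery ranges, pediatric relaxometry, atrial
  and aortic LMS grids, aortic/pulmonary regression fits, LV-volume and
  LA-volume centile tables), not the full catalogue; additional tables in
  the same CSV+sidecar format are picked up through
  `load_registry(extra_dir = ...)`.
* LMS parameters are *evaluated*, never fitted; fitting L/M/S from raw data
  is out of scope.
* No DICOM or image segmentation: the fractal-dimension code consumes binary
  masks the user already produced.
* Unit handling is declarative (units travel with tables and parameters);
  there is no automatic unit conversion.
* The flagged atrial LMS panels carry a defect of the source document, as
  described above.
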