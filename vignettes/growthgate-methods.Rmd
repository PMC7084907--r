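---
title: "Reference bands for adult anthropometry: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference bands for adult anthropometry: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthgate)
```

`growthgate` turns an archive of hand-keyed adult health records into
age-specific reference bands and uses those bands to flag suspicious
measurements at the point of data entry. This vignette explains the
statistical machinery, the defaults and why they are what they are, what the
synthetic generator does and does not emulate, and the numerical corner
cases.

## The preprocessing contract

Raw archives mix genders, contain minors, incomplete check-ups and
physically impossible values. `preprocess_pipeline()` applies four steps in
a fixed order — completeness, age window (default 20+, upper bound open),
gender selection, plausibility bounds — and records an audit trail in which
every step satisfies `n_in = n_kept + n_dropped` and consecutive steps
chain. Two properties matter and are enforced by tests: the pipeline is
idempotent (its output passes unchanged), and the surviving *set* does not
depend on the order of the completeness and age filters, only the audit
does.

Outlier removal is deliberately dumb: closed per-measure intervals (height
[120, 210] cm, weight [25, 250] kg, BMI [10, 70], waist [40, 200] cm, hip
[50, 200] cm) wide enough that only impossible entries are cut. A published
reference pipeline cannot rest on eyeballing; a stated rule can be audited
and overridden. Statistically *suspicious* (as opposed to impossible) values
are the gate's job, downstream, not preprocessing's.

## Quantile curves

For every age present in the cohort we compute seven percentiles
(5, 10, 25, 50, 75, 90, 95 — the levels conventional for clinical growth
charts) and the arithmetic mean. The quantile rule is pinned: linear
interpolation of order statistics with plotting position `h = (n-1)p + 1`
(R's `type = 7`). Any of the common rules would do; what matters is that one
is named, tested, and used identically in the per-age, binned and acceptance
paths.

The age grid is the set of *observed* ages, not a filled 20–100 grid.
Smoothing interpolates only where data exist; the band predictor handles
unobserved ages explicitly (linear interpolation inside the grid, the
enclosing 5-year bin outside it, `NULL` — and thus fallback to global
bounds — where even the bin is empty or degenerate).

## Loess smoothing

`loess_smooth()` is a classic local polynomial smoother evaluated at the
design points: for each age, a weighted least-squares polynomial over the
`ceiling(span * n)` nearest grid ages, with tricube distance weights
multiplied by per-age record counts, zero robustness iterations. Count
weighting matters because the age distribution is strongly right-skewed:
ages past 80 may carry one or two records each, and unweighted smoothing
would let them deflect the curve. Degenerate neighbourhoods (all tied ages,
or too few points with positive weight) fall back to the local weighted mean
and are logged rather than erroring.

Defaults for the stored curve set: `span = 0.75`, `degree = 2` — the classic
loess settings, flexible enough to follow the curvature of the height-age
relationship. Independent smoothing of each percentile can make adjacent
curves cross where data are thin; non-crossing is restored by sorting the
smoothed values at each age (rank-preserving, order n log n, trivially
testable), and every age where sorting changed anything is logged. Joint
constrained smoothing would avoid the issue at far greater complexity; at
these sample sizes the sort is a no-op almost everywhere except the sparse
old-age tail.

## Segmentation

The age axis is segmented by an exhaustive search over integer breakpoint
pairs `(b1, b2)` (candidates [25, 95], each segment at least 5 years — the
bin granularity), fitting the continuous piecewise-linear basis
`{1, a, (a-b1)+, (a-b2)+}` by weighted least squares and keeping the global
SSE minimiser. The search space is ~2,500 pairs, so brute force is exact,
deterministic and fast; ties are broken toward the lexicographically
smallest pair (with a 1e-8 relative SSE tolerance so that floating-point
noise cannot mask a tie, e.g. on perfectly linear input). Slopes map to
labels through two thresholds, `t_stable = 0.05` and `t_sharp = 0.3`
cm/year: the textbook adult rate of roughly 1 cm per decade (0.1 cm/year)
must classify as `slow_decline`, and the much faster loss seen past the
mid-sixties as `sharp_decline`.

One design choice here deviates from an obvious default and deserves its
reasoning. The curve handed to the breakpoint search is smoothed with a
local-**linear** loess (`degree = 1`, same span and count weights), not the
degree-2 smoother used for the stored display/band curves. The model being
fitted to that curve is piecewise-linear; a local-quadratic smoother whose
neighbourhoods straddle a knee systematically displaces it — on the
*noiseless* expected mean curve of the calibrated generator, degree-2
smoothing at span 0.75 shifts the upper knee by about +4 years, and across
40 simulated cohorts of n = 14,000 the (49, 64) knots are recovered within
±3 years in only a third of runs. With a local-linear input curve the same
search recovers both knots within ±3 years in ~85% of runs (median (49,
62)). Matching the smoother's local model to the segmentation model is the
principled fix; the band curves are unaffected.

A related caveat: estimating the *middle-segment slope* by an ordinary
least-squares line through the smoothed median between the knots inherits a
corner-rounding bias from any linear smoother whose bandwidth is comparable
to the 15-year segment — both rounded corners steepen the line, so the
estimator centres near 1.3–1.4 cm/decade rather than the generating 1.0
under the default settings. The package reports what the estimator computes;
users comparing against a generating rate should prefer the piecewise fit's
own middle slope, which does not have this bias.

## Acceptance bands and the gate

The band hierarchy is total: personal history (median of at least `k = 1`
validated prior values, ± 3 cm for height, ± 10–15% for mass-related
measures), else the cohort reference (smoothed 5th–95th percentile curves by
default — configurable, e.g. 1st–99th where false flags are costlier), else
the global plausibility bounds; whatever wins is intersected with the global
bounds. For height histories the lower bound is widened by an ageing
allowance — elapsed years × the reference slope of the segment containing
the patient's current age — so genuine height loss in older patients is not
flagged. Decisions use the closed interval; boundary values are accepted.
The gate never alters a value: suspicious entries are returned for human
re-measurement, and only human-validated records may re-enter the
reference, via full rebuilds (batch threshold 500, or forced). Full rebuild
rather than incremental quantile maintenance is a deliberate simplicity
choice at desk scale (n ~ 10^4, rebuild well under a second).

With a (5, 95) band, clean data are flagged at a nominal ~10% (two 5%
tails); measured rates on fresh synthetic cohorts sit at 10–12%, the excess
coming from band-estimation error at sparse ages. A cm→inch unit error maps
adult heights to ≤ 73, far below any adult band, so detection of that error
class is effectively certain — the asymmetry motivating the whole
at-the-source design.

## The synthetic generator

No real archive ships with the package, so the generator emulates the
structure such archives exhibit, with every number pinned in
`adult_male_preset()`:

* **Mean height**: piecewise-linear, 163 cm (midpoint of the adult IQR
  158–168) flat to age 49, −0.1 cm/year to 64, −0.5 cm/year beyond. The
  third slope is invented — sources describe the post-65 drop only
  qualitatively — and is chosen so the three segment labels are separable
  under the default thresholds.
* **Within-age noise**: Gaussian, SD = 10/1.349 ≈ 7.413 cm so the
  within-age IQR is 10 cm. The Gaussian family is an assumption; the
  IQR-based calibration is exact only under it.
* **Clipping**: heights truncated to [135, 185] cm, the recorded extremes,
  making the 50 cm population range a hard invariant.
* **Ages**: truncated exponential on [20, 100]; the scale (~10.55 y) is
  solved at preset construction so the expected number of *integer* ages
  above 80 in a cohort of 13,932 equals 37 (the tail equation uses the
  80.5 threshold because ages are rounded).
* **Errors**: each record corrupted with probability 0.12 — the reported
  manual-entry error rate — by one of four types (cm→inch, last-two-digit
  transposition, ±100 offset, random keystroke), with ground-truth labels;
  a transform that happens to be a no-op is replaced by the ±100 offset so
  labels are always sound. Corrupted records are demoted to unvalidated.
* **Other measures** (weight, waist, hip, BMI-from-weight-and-height) are
  plausible but *uncalibrated*; they exist so completeness filtering and
  multi-measure gating have material, and carry no distributional claims.

What passing tests on this generator shows: the pipeline recovers known
quantiles, knots and rates from data with the right marginal structure.
What it does not show: robustness to features real archives have and the
generator lacks — secular height trends across birth cohorts (a
cross-sectional decline can reflect taller younger generations rather than
shrinkage), within-patient correlation and repeat visits, missingness that
is informative rather than independent, digit-preference heaping, and
gender/location strata with their own calibrations.

## Numerical and format choices

* Deterministic everywhere: generation and corruption take explicit seeds;
  smoothing, search and gating are seed-free.
* Reference models serialize to human-diffable JSON at full floating-point
  precision. The volatile build timestamp is *not* serialized, so identical
  inputs yield byte-identical model files — reproducibility is checked by
  tests at file level.
* CSV interchange: UTF-8, header required, ISO-8601 dates; empty cells and
  `NA` both read as missing; missing is written as an empty cell, never 0.
  Gender tokens are normalized through a fixed case-insensitive table
  ({m, male, 1} / {f, female, 2}); unknown tokens are errors or logged
  skips, never guesses. The export schema of any particular archive system
  is unknown; the header used here is the package's own documented
  convention, and `read_records(schema = ...)` maps foreign column names
  onto it.
* Problem sizes in the test suite were chosen to keep the full run around
  half a minute while leaving Monte-Carlo margins comfortable: cohorts of
  1,000–14,000 for pipeline and recovery checks, 50,000 for distributional
  calibration, 10,000 for gate calibration.

## Known limitations

Cross-sectional curves confound age and birth-cohort effects; the package
documents but cannot remove this. Breakpoint uncertainty is not quantified
(no confidence intervals) — the fit is an estimator, not an inference
procedure. The fallback hierarchy stops at gender + age: geography is a
plausible further axis but no location field is defined in the record
schema. Only the male-height pattern is calibrated and validated end to end;
the machinery is generic over measures and genders, but bands for other
measures inherit only the generic tolerances, not calibrated ones.
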