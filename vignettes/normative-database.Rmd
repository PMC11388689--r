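---
title: "Building age-corrected perimetric reference databases with vfnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building age-corrected perimetric reference databases with vfnorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfnorm)
```

## The problem

Static automated perimetry measures differential light sensitivity (in dB of
stimulus attenuation) on a fixed grid of test points. Clinical
interpretation rests on a *reference database* (RDB): for every test point,
the range of sensitivities found in healthy subjects of a given age, and
derived limits that flag a measured field as abnormal at the 5/2/1/0.5%
levels. This package implements the full construction of such an RDB — from
raw per-subject test records through eligibility and reliability quality
control, pointwise age regression, nonparametric limit estimation, and the
deviation indices computed against the finished model — together with a
resampling analysis of how large the normative cohort must be.

Because normative datasets of this kind are typically proprietary, the
package also ships a synthetic cohort generator calibrated to the summary
statistics such a study publishes. The generator defines the study
conditions under which the pipeline is tested; it is not a tuning knob.

## Test patterns

`build_pattern()` constructs the two supported grids in a canonical
right-eye frame (x > 0 nasal, y > 0 superior, integer degrees):

* **24-2**: both coordinates odd multiples of 3 with `|x| + |y| <= 30` and
  `|y| <= 21`, minus the two temporal points at 27 degrees — the standard
  54-point chart with rows 4/6/8/9/9/8/6/4 and two extra nasal points at
  `(27, ±3)`. The points at temporal 15 degrees, `y = ±3`, overlie the
  physiologic blind spot; they are flagged and excluded from every analysis
  (52 analyzed points) but never removed from the record.
* **10-2**: odd-integer coordinates with `x² + y² <= 89`, 17 points per
  quadrant (68 points, all analyzed, all within 9 degrees of fixation).
  The exact vendor layout of the 10-2 is not published; this radial rule
  reproduces the standard point count, and any alternative layout can be
  supplied as a JSON pattern file (`read_pattern()`), to which all
  downstream code is agnostic.

Left-eye records are mirrored onto the canonical frame
(`mirror_to_canonical()`, an involution), since the pipeline pools a
randomly selected eye per subject.

## The synthetic cohort generator

A subject *i* tested at point *p* yields

```
y_ip = B_p - beta_p (age_i - A_ref) + g_i + eps_ip,  clipped to [0, 40] dB
```

* `B_p` — base map: a hill of vision, affine in eccentricity
  (0.25 dB/degree by default), with its mean over analyzed points pinned to
  the target mean sensitivity (29.1 dB for 24-2, 32.4 dB for 10-2).
* `beta_p` — decline map (dB/year): a smooth field, affine in eccentricity
  with a superior-hemifield increment, rescaled so that its mean over
  analyzed points is exactly 0.06 (24-2) / 0.05 (10-2) dB/year and its
  across-point SD exactly 0.01 dB/year. For the 24-2 the steepest point is
  pinned so that the maximum 30-year decline is exactly 2.5 dB. The
  published "(0.01)" accompanying the mean decline is treated as an
  across-point SD rather than a standard error; this choice only shapes the
  default truth maps.
* `g_i ~ N(0, 0.3 dB)` — a general-height offset shared across points, eyes
  and patterns, representing diffuse between-subject offset.
* `eps_ip` — left-skewed noise with SD `sigma_p = sigma0 + sigma1 * ecc(p)`:
  `eps = sigma_p (Z (1 - gamma) - gamma (G - 1)) / sqrt((1-gamma)² + gamma²)`
  with `Z` standard normal and `G ~ Gamma(1, 1)`. The blend has exactly
  zero mean and variance `sigma_p²` for any `gamma in [0, 1)`; `gamma > 0`
  lengthens the lower tail (sensitivity losses), as perimetric normal data
  show. Defaults: `gamma = 0.35` (24-2) and `0.20` (10-2), making the 24-2
  asymmetry more pronounced.

`sigma1` is solved in closed form so that the analytic between-subject SD of
mean sensitivity,

```
SD(MS)² = mean(beta)² Var(age) + gh_sd² + sum(sigma_p²)/N²,
```

reproduces 1.3 dB (24-2) and 1.0 dB (10-2) under the configured age-bin
design; `Var(age)` is the exact variance of integer ages drawn uniformly
within the seven bins (22–29 … 80–89) at the configured counts
(59/51/56/52/62/53/23, mean 51.9, SD 18.7 years). The foveal threshold gets
its own linear-in-age model with residual SD calibrated the same way
against the published totals (34.1 (4.3) and 34.0 (4.7) dB). The reference
age `A_ref = 52.3` years makes `B_p` interpretable as the cohort-mean
surface. Ages in the open-ended 80+ bin are drawn uniformly on 80–89 (the
within-bin distribution is unstated in the source cohort; uniform is
assumed and documented here).

A full simulated enrollment (`simulate_cohort()`) adds 20
enrolled-but-excluded subjects with the published reason structure
(6/3/4/5/1/1), flags 15 included subjects as monocular-only, simulates
practice and study tests for both eyes with randomized within-pair order,
draws reliability indices from Beta distributions whose defaults make gate
failures rare (the source study repeated no tests), and runs the
up-to-3-attempts retest loop on study tests. Everything is deterministic
given the configured seed.

**What the generator does not emulate:** the thresholding staircase and
stimulus timing (thresholds are drawn directly from the noise model, not
simulated as staircases), blind-spot physiology (flagged points are
simulated like ordinary points but excluded from all analyses), spatial
correlation of noise beyond the shared general-height term, learning or
fatigue effects, and diseased fields. Passing tests therefore demonstrate
the correctness and calibration of the *pipeline*, not device-level realism
of individual fields.

## Quality control

Boundary semantics are inclusive of the printed limits: age ≥ 22 passes;
acuity 20/40 (logMAR `log10(2)`) passes; IOP ≤ 21 mmHg passes; |SE| ≤ 6 D
and |cyl| ≤ 2.5 D pass. The reliability gate fails a test iff any of
fixation losses, false positives or false negatives strictly exceeds 25%
(exactly 25% passes), and is monotone in each rate. Retesting re-runs both
eyes (binocular acquisition) up to three attempts. `apply_exclusions()`
conserves counts exactly: enrolled = included + sum over reasons.

## The normative model

`build_reference_database()` is a two-pass construction:

1. **Fit.** OLS of threshold on age at each analyzed point (one
   multivariate `lm`), plus the foveal regression. Per-point age-corrected
   residuals are pooled across ages — the spread is assumed homoscedastic
   in age, since nothing in the source analysis describes age-dependent
   spread — and tabulated as Hazen quantiles at
   0.5/1/2/5/50/95/98/99/99.5%. Residual variances `s2_p` are floored at
   0.01 dB² so that degenerate (noise-free) inputs keep MD/PSD weights
   finite.
2. **Indices.** Every cohort subject's TD/GH/PD/MD/PSD is computed against
   the surfaces fitted in pass 1, and global limits are tabulated: MD and
   foveal deviation at the lower 5/2/1/0.5% tail, PSD at the upper tail,
   and per-point PD quantiles alongside the TD (residual) tables.

The quantile rule is Hazen (plotting position `(i − 0.5)/n`, linear
interpolation) throughout — symmetric and standard for reference intervals.
The 50th-percentile surface is taken to be the regression prediction rather
than per-age empirical medians: cross-sectional regression is the only
age-correction the construction defines, and pooled limits (not per-decade
bins) follow from the same choice. TD probability maps use the lower tail
only, matching clinical convention; the upper tail is stored but unused by
default.

The general-height rank (`k = ceiling(0.15 N)`, i.e. the 8th best of 52 or
11th best of 68) and the variance-weighted MD/PSD formulas follow the
conventions established for clinical perimetry software; device vendors do
not publish their exact weighting, so both are configurable and the
analysis report notes them as conventions.

## Reference limits and sample size

`percentile_ci()` gives the distribution-free order-statistic CI for a
percentile: ranks `qbinom((1±conf)/2, n, p)` clamped to `[1, n]` (at
n = 1000, level 5%, the 95% CI is the 37th to 64th order statistic).
Samples below 20 return the full range with a warning. Exact coverage of
this rule is ≈95% for moderate `n·p` and can drop below it for extreme
percentiles at small `n·p` — which is precisely the phenomenon the
sample-size analysis quantifies.

`run_sample_size_simulation()` replicates a reference value set three
times, draws simulated datasets with replacement, and reports the fraction
of datasets in which the 95% CIs of the 0.5th/1st/2nd/5th percentiles are
pairwise disjoint for adjacent pairs (all-pairs mode available; adjacent
pairs are the binding comparisons). One subtlety drives the design: for a
*global* parameter a cohort of n subjects contributes n values, and at
n = 356 the lower CI ranks of the 0.5th and 1st percentiles both clamp to
the first order statistic, so their CIs can never separate — no overlap
criterion can be met by global parameters at that size. *Pointwise*
parameters (total and pattern deviation) contribute one value per analyzed
point, i.e. 52 × n values for the 24-2, and their adjacent extreme-percentile
CIs separate cleanly at n = 356. The `values_per_n` argument expresses
this multiplicity, and the package reproduces the "CIs seldom overlap at
n = 356" decision rule as a property of pointwise parameters. Sampling is
from the replicated vector exactly as described even though replication
leaves the empirical distribution unchanged — fidelity to the stated
procedure.

## Numerical choices and degenerate inputs

* Calibration identities (slope-map mean/SD/max) hold to 1e-12 by
  construction; they are solved in closed form, not iteratively.
* Noise-free cohorts produce zero residual limits and floored variances.
* Classification is inclusive at limits and errors on non-monotone limit
  vectors; model files re-validate all invariants on read.
* The eligibility acuity cutoff is `log10(2)` (= 0.30103), not 0.3, so that
  20/40 passes; all comparisons carry a 1e-9 tolerance against rounding.
* Seeds: `simulate_cohort()` seeds the RNG itself from its config;
  eye selection and the sample-size simulation take explicit seeds.

## Problem sizes used in the test suite

Structural tests use 50-subject cohorts with the same age-bin proportions
as the default design; calibration and recovery tests use the full
356-subject design across 10–20 seeds; the quantile oracle runs 1000 random
instances; CI coverage uses 2000 Gaussian replicates at n = 356; the
sample-size property uses 50–200 simulated datasets per grid point. These
sizes keep the whole suite under half a minute while leaving all
calibration checks comfortably inside their tolerances.

## Known limitations

* The 10-2 layout is a standard-count stand-in, swappable via JSON.
* Pointwise noise is independent across points given the general-height
  offset; real fields show additional local spatial correlation, so
  synthetic PSD distributions are somewhat narrower than clinical ones.
* The model stores pooled age-corrected limits; per-decade limit tables are
  out of scope.
* Blind-spot stimulus mechanics, staircase algorithms, imaging-based
  screening and device hardware are out of scope throughout.
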