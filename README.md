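# vfnorm

Tools for constructing and applying **age-corrected normative reference
databases (RDBs) for static automated perimetry** on the 24-2 and 10-2 test
patterns, written for biostatisticians and vision scientists who need a
tested, reproducible implementation of the whole pipeline: test-pattern
geometry, quality control, pointwise age regression, nonparametric reference
limits, deviation indices, and the resampling sample-size analysis that
justifies a normative cohort size.

Because normative visual-field datasets are rarely public, the package ships
a **calibrated synthetic cohort generator** that emulates the statistical
structure such a study produces — a 356-subject cohort in seven age bins, an
age-declining hill of vision, and eccentricity-dependent, left-skewed
pointwise noise — so every stage of the pipeline is testable end to end
without any data download.

## The model

For each test point *p* of a pattern (52 analyzed points on the 24-2, 68 on
the 10-2), threshold sensitivity in dB is modelled cross-sectionally as a
linear function of age:

```
y_ip = alpha_p + b_p * age_i + e_ip
```

fitted by OLS per point; `alpha_p + b_p * age` is the age-corrected 50th
percentile surface, and the pooled age-corrected residuals `e_ip` define the
pointwise reference limits, taken as nonparametric (Hazen) quantiles at the
5%, 2%, 1% and 0.5% levels. From a test against the model the package
computes the standard indices:

- **TD** (total deviation): `td_p = y_p - (alpha_p + b_p * age)`
- **GH** (general height): the k-th best TD, `k = ceiling(0.15 N)`
- **PD** (pattern deviation): `pd_p = td_p - GH`
- **MD** (mean deviation): `sum(td_p / s2_p) / sum(1 / s2_p)`
- **PSD**: `sqrt( mean(s2) * sum((td_p - MD)^2 / s2_p) / (N - 1) )`

with `s2_p` the per-point residual variance. Global limits for MD (lower
tail), PSD (upper tail) and the foveal threshold complete the model. A
distribution-free order-statistic procedure (`percentile_ci`,
`run_sample_size_simulation`) reproduces the resampling argument that a
356-subject cohort suffices for stable extreme-percentile limits of
pointwise parameters.

## Worked example

```r
library(vfnorm)

cohort   <- simulate_cohort(default_cohort_config(seed = 1))
screened <- apply_exclusions(cohort)
screened$tally
#> enrolled 376 = included 356 + excluded 20
#>           ocular_condition           re_outside_range
#>                          6                          3
#> eye_not_eligible_committee                 incomplete
#>                          4                          5
#>         intolerant_imaging                  iop_ge_22
#>                          1                          1

set.seed(2)
model <- build_reference_database(screened$included, "24-2")
model
#> vf_norm_model 24-2: n = 356, 52 analyzed points, levels 5/2/1/0.5%
round(mean(-model$slope, na.rm = TRUE), 4)   # mean age decline, dB/year
#> [1] 0.0611
```

The tally reproduces the enrollment accounting of a 376-subject screening
(20 excluded for six reasons, 356 included), and the mean fitted decline of
~0.06 dB/year is the cross-sectional aging effect the cohort was calibrated
to. Analyzing one simulated test against the model:

```r
test <- test_record(cohort$tests, 714)   # a study 24-2 test, right eye
age  <- cohort$subjects$age[cohort$subjects$subject_id == test$subject_id]
analyze_test(test, model, age)
#> vf_deviation 24-2 (age 25): MD 0.54 dB [ns], PSD 4.22 dB [ns], GH 4.44 dB
#> foveal deviation 3.42 dB [ns]
#> total deviation (dB):
#>      .     .  -6.9   4.3  -1.2   2.8     .     .     .
#>      .   4.4  -3.8   3.9   0.2  -9.1   6.4     .     .
#>   ...
#> TD probability (. ns, 5/2/1 = p<.05/.02/.01, * = p<.005):
#>        .  .  .  .
#>     .  .  .  .  2  .
#>   ...
```

MD near 0 dB and an `ns` classification are what a healthy test drawn from
the same population as the model should produce; the one point flagged `2`
(p < 0.02) is the expected false-positive behaviour of pointwise 5%/2%
limits on 52 points. A command-line wrapper over the same functions is at
`system.file("cli", "vfnorm.R", package = "vfnorm")` with subcommands
`simulate`, `build-rdb`, `analyze` and `samplesize`.

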