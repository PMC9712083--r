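# bonechron

Did a species really survive as late as its sedimentary-DNA record suggests —
or do the late detections come from DNA shed by long-dead remains still
decaying on the landscape?

Sedimentary ancient DNA (eDNA) cannot be directly dated: a detection is dated
by its host sediment, and any tissue of the species — carcasses, bones,
antlers, dung — contributes DNA for as long as it persists. On cold Arctic
landscapes, exposed large-mammal bones persist for millennia, so eDNA can keep
recording a species thousands of years after its extinction. `bonechron`
implements the three-stage inference chain needed to evaluate that
alternative for any dated occurrence record:

1. **Taphonomic persistence regression.** The duration an exposed bone
   persists is modelled as log-linear in local mean annual temperature:
   `log10(T_persist) = β0 + β1·MAT + ε`, fitted by OLS to the oldest dated
   surface bone per region, separately for bones confidently never buried and
   for the broader "potentially never buried" class. Predictions at a new MAT
   come with mean-line confidence or new-observation prediction intervals.
2. **Extinction-date estimation.** From a dated sighting record
   `a_1 > … > a_n` (cal yr BP), each older sighting defines a sighting rate
   `λ_i = (n−i)/(a_i − a_n)`; the persistence probability `(1−λ_i)^t` drops
   below `α` at the offset `ln α / ln(1−λ_i)` past the last sighting. The
   single-reference estimates are combined with inverse-distance weights
   `1/(a_i − a_n)`, and dating error is propagated by Gaussian resampling of
   every age (σ = 2σ/2) — the GRIWM family of estimators. Fossil and eDNA
   series are estimated separately.
3. **Temporal-mixing test.** A persistence window extends from the median
   fossil-based extinction estimate toward the present by the predicted bone
   persistence at the region's site temperature; every post-fossil eDNA
   detection is classified into the tightest of three nested windows
   (never-buried mean, never-buried upper bound, potentially-never-buried
   upper bound) or flagged `outside` — genuinely anomalous under the
   dead-tissue explanation.

A synthetic-data generator (`gen_bone_table()`, `gen_occurrence_series()`,
`gen_mixing_study()`) produces both table types with known ground truth, so
the whole chain is validated by simulation with no external downloads.

## Worked example

```r
library(bonechron)
library(dplyr)

# 1. persistence regression on a synthetic bone table
bones <- gen_bone_table(bone_gen_config(n = 30, seed = 42))
fit <- fit_persistence(bones, "never_buried")
fit
#> Bone persistence regression (never_buried)
#>   log10(persistence yr) = 2.5208 -0.0591 * MAT   (n = 15)
#>   R^2 = 0.948, slope p = 9.46e-10, residual variance = 0.0325

predict_persistence(fit, mat = -13.3)
#> # A tibble: 1 × 6
#>     mat mean_persistence upper_ci ci_level interval_kind   extrapolated
#>   <dbl>            <dbl>    <dbl>    <dbl> <chr>           <lgl>
#> 1 -13.3            2024.    2983.     0.95 mean_confidence FALSE
```

At a site with MAT −13.3 °C this fit expects bones to persist about 2.0 kyr on
average (upper 95% bound ≈ 3.0 kyr): eDNA deposited up to ~2–3 kyr after
extinction needs no living animals.

```r
# 2. extinction date from a fossil series ending at a true extinction of 11 kyr BP
occ <- gen_occurrence_series(series_gen_config(record_start = 21000, seed = 7))
est <- estimate_extinction(filter(occ, source == "fossil"),
                           estimator_config(n_resamples = 1000, seed = 1))
est
#> Extinction estimate: synthetic_region (fossil records, n = 122)
#>   median 10.72 kyr BP (mean 10.73), 95% CI [11.14, 10.28] kyr BP

# 3. full pipeline: persistence windows + eDNA classification, per region
study <- gen_mixing_study(n_regions = 3, seed = 3,
                          series_config = series_gen_config(record_start = 21000))
reports <- run_pipeline(study$bones, study$occurrences, study$sites,
                        config = estimator_config(n_resamples = 500, seed = 1))
reports[[1]]
#> Temporal-mixing report: region_01
#>   fossil extinction median 10.73 kyr BP; windows down to 8.28 / 7.65 / 7.65 kyr BP
#>   eDNA: within_mean = 108, within_upper = 1, within_upper_potential = 0, outside = 0
```

Region 1's eDNA detections all fall inside the expected persistence windows —
the pattern consistent with dead-tissue DNA input, not late survival. `tidy()`
and `glance()` return these results as tibbles; `autoplot()` draws the
regression band, the resample distribution, and the per-region timeline.

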