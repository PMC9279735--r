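# rtflow

Decision support for adaptive radiotherapy (ART) of head-and-neck cancer:
track, per treatment fraction, the dose a patient's targets and organs at
risk are actually accumulating, flag when monitored dose parameters cross
clinically chosen thresholds, and forecast threshold crossings up to four
fractions ahead.

During a 30–35 fraction head-and-neck course the anatomy changes — tumours
regress, parotid glands shrink and drift medially, patients lose weight and
sit differently in the mask. A plan that was acceptable at simulation can
silently lose target coverage (V95 below 95%) or overdose a spared parotid
(mean dose above its 20/21/26 Gy goal). `rtflow` automates the quantitative
side of the daily replanning decision:

1. **Deformable registration** — a multi-resolution optical-flow algorithm
   (brightness-constancy force, Gaussian field regularisation, image
   pyramid) maps the planning CT onto each daily CBCT, producing a dense
   deformation vector field `u` with `x + u(x)` the daily position of the
   tissue at plan position `x`.
2. **Dose mapping** — with the planned dose held fixed in room coordinates,
   each tissue element of a structure receives the full-course-equivalent
   dose `d̂_f(x) = D_plan(x + u_f(x))` on day `f` (Lagrangian accumulation,
   no dose recalculation).
3. **DVH and dose parameters** — cumulative DVHs and the monitored
   parameters (`V95`, `Dmean`, `Dmax`, `D1cc`, hotspot) for the
   day-of-treatment dose `DP_day` and the projected cumulative dose

   `D_sum,k(x) = (1/N) Σ_{f≤k} d̂_f(x) + ((N−k)/N) d̂_k(x)`,

   i.e. the course outcome if today's anatomy persisted to the end.
4. **Endpoints** — warning and adaptation thresholds per structure:
   `V95 < 95%` / `< 93%` for targets, and for OAR dose limits an adaptation
   level exactly 10% above the warning level (`DE_10 = 1.10 · DE_0`), with
   plan-dependent parotid rules (20 / 21 / 26 Gy). Crossing fractions `Fx`
   are read off the `DP_sum` trajectory.
5. **Forecasting** — an ordinary-least-squares trend of `DP_sum` predicts
   the next four fractions (needs ≥ 5 processed fractions), plus the
   anchored accuracy evaluation `ΔDP_sum[Fx−i] = mean(pDP_sum[Fx−i] −
   DP_sum[Fx])` with 95% t-confidence intervals.
6. **Registration QA** — per-structure normalized cross-correlation
   (flag below 0.85) and maximum displacement (flag above 7 mm).

Everything is testable without patient data through a synthetic phantom
(`make_plan_phantom()`, `simulate_course()`) with exact analytic ground
truth for deformations, doses and trends. I/O covers DICOM-RT objects
(CT series, RT Structure Set, RT Dose — explicit VR little endian) and a
portable NIfTI + JSON fixture format.

## Worked example

A 12-fraction phantom course in which the left parotid drifts medially into
the dose gradient:

```r
library(rtflow)

cfg    <- phantom_config(dim = c(64, 64, 40), spacing = c(3, 3, 3),
                         n_fractions = 12)
bundle <- make_plan_phantom(cfg, seed = 2)
truth  <- course_truth(cfg, parotid_drift_mm = 1.8, setup_sd_mm = 1.0, seed = 3)
course <- simulate_course(bundle, truth)

report <- process_course(bundle, course$daily)
subset(report$violations, structure == "parotid_left")
#>      structure metric      level threshold fx dp_at_fx cumulative_dose_gy eot_violation
#> 1 parotid_left  Dmean    warning        20  6    20.89                 30          TRUE
#> 2 parotid_left  Dmean adaptation        22  7    23.61                 35          TRUE
```

The gland's projected cumulative mean dose crosses its 20 Gy warning
endpoint at fraction 6 and the 22 Gy (`1.10 × 20`) adaptation endpoint one
fraction later — in a clinic this is the point where the treatment team
reviews the trend and decides whether to replan. `report$fractions` holds
the `DP_day`/`DP_sum` trajectories behind those events, `report$qa` the
per-fraction registration confidence metrics, and `report$predictions` the
four-fraction-ahead forecasts:

```r
tr <- subset(report$fractions, structure == "parotid_left" & metric == "Dmean")
fit <- fit_predict(tr$dp_sum, tr$fraction)
tidy(fit)
#> # A tibble: 2 × 2
#>   term      estimate
#>   <chr>        <dbl>
#> 1 intercept     6.31
#> 2 slope         2.06
autoplot(fit)   # observed trend + dashed forecast
```

The fitted trend gains about 2.1 Gy of projected mean dose per fraction;
the gland crosses its warning endpoint at fraction 6 of 12, after 30 Gy of
the 60 Gy course. (Numbers vary slightly with the seeds; the crossing
fraction is reproduced within one fraction of the simulation's ground
truth.)

A thin CLI wraps the same functions for shell use:
`inst/scripts/rtflow phantom|process|report|predict`.

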