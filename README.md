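# footstress

Acute-stress sensing from the feet, for seated office-style work: an R
implementation of a plantar-pressure + ankle-motion stress detection
pipeline, from raw sensor streams to cross-validated classifiers and an
hourly field-study stress metric.

When people experience acute stress while sitting, their feet give it
away: loading shifts toward the forefoot, the centre of pressure moves
anteriorly, the resting leg angle changes, and some people tap or shake
a foot. `footstress` turns those observations into a measurement
pipeline for a 16-sensor pressure insole (50 Hz) and an ankle-worn
3-axis accelerometer (50 Hz), with a wrist accelerometer (32 Hz) added
for all-day field use. The package is aimed at researchers in wearable
affective computing who want a reference implementation of the method
that runs end to end on fully synthetic, ground-truth-labelled data —
no human-subject recordings are required (or shipped).

## The method

All signals are cut into non-overlapping 10 s windows. Per window, ten
features are computed:

| Feature | Definition |
|---|---|
| A1, A2, A3 | window means of forefoot (`P_F = Σ_{i=1..12} P_i`), rearfoot (`P_R = Σ_{i=13..16} P_i`) and total pressure, after a 1 s trailing moving average on each channel |
| B1, B2 | centre of pressure, `XCoP = (Σ_F P_i x_i + 3 Σ_R P_i x_i) / (P_F + 3 P_R)` and the analogous `YCoP` (mm; rearfoot sensors weighted ×3) |
| C1–C3 | per-axis means of the raw ankle acceleration (g); gravity is kept, since its projection encodes leg posture |
| D1, D2 | median and dominant frequency (Hz) of `V3D`, the axis-inverted 3D norm: each axis in turn is reflected as `a_inv = 2·max(a) − a`, the norm with the largest peak-to-peak is kept, and a one-sided periodogram above 0.5 Hz yields the half-power crossing (D1) and the peak bin (D2) |

A two-class linear discriminant (stress vs relaxation) is trained on
any feature subset and evaluated with **leave-one-user-out (LOUO)**
cross-validation: per-user window accuracy, mean ± SD across users, an
accuracy curve over window position, and a paired t-test for the
separation sharpness between conditions. Ground-truth windows come from
tasks whose self-rating agrees with the intended condition (rating > 4
on stress tasks, < 4 on relaxation tasks, 1–7 Likert scale), with the
first and last 60 s of every task discarded.

In field mode, wrist accelerometry is segmented into 5 s windows and
classified by **acceleration vector change** (AVC, m s⁻³): walking
(≥ 2), standing (< 0.1), sitting ([0.1, 0.2)), with the uncovered gap
labelled `unknown`. Foot windows fully inside sitting time are
classified by a trained model, and each hour is summarised by the
stress ratio

    R_S = (stressed sitting windows) / (total sitting windows),

which is correlated (Pearson) against the hourly self-reported stress
level (SRSL).

The synthetic generator (`generate_session()`, `generate_field_day()`)
plants all four stress signatures with switchable magnitudes, records
complete ground truth, and is bit-reproducible under a fixed seed.

## Worked example

Simulate a five-user laboratory cohort (four 5-minute tasks each,
alternating stress/relaxation), extract features, and evaluate the
four-feature model with leave-one-user-out validation:

```r
library(footstress)

tab    <- generate_cohort_table(seed = 42, n_users = 5)
report <- leave_one_user_out(tab, c("A1", "B2", "C3", "D1"))
report
#> <leave-one-user-out: A1+B2+C3+D1 | mean accuracy 100.0% (SD 0.0) over 5 users | separation p = 0>
report$per_user
#>   participant_id n_windows accuracy
#> 1            P01        72      100
#> 2            P02        72      100
#> 3            P03        72      100
#> 4            P04        72      100
#> 5            P05        54      100
```

Each row is one held-out participant; `n_windows` counts their labelled
10 s windows (P05 lost one ambiguously rated task to the ground-truth
rule) and `accuracy` is the percentage classified correctly by a model
trained only on the other users. At the generator's default effect
sizes the classes separate completely; `separation p` is the paired
t-test on per-user stressed-fractions under the two conditions.

Then run a synthetic 8 h field day through posture gating and the
hourly stress ratio:

```r
day   <- generate_field_day(seed = 42)   # planted intensities ramp 0.1..0.8
model <- fit_lda(tab, c("A1", "B2", "C3", "D1"))
hours <- field_hours(day$insole, day$ankle, day$wrist, model,
                     default_layout(), srsl = day$srsl)
head(as.data.frame(hours)[, c("hour", "n_sitting", "n_stressed", "r_s", "srsl")], 4)
#>   hour n_sitting n_stressed        r_s srsl
#> 1    0       288         25 0.08680556    2
#> 2    1       288         63 0.21875000    1
#> 3    2       288         82 0.28472222    3
#> 4    3       288        117 0.40625000    3
correlate_field(hours)$r
#> 0.914
```

`R_S` climbs with the planted hourly stress intensity, and correlates
with the self-reports at r = 0.914 over the 8 hours.

A command-line wrapper over the same functions lives at
`inst/cli/footstress.R` (subcommands `synth`, `extract`, `train`,
`evaluate`, `field`); every run writes a `manifest.json` with the
configuration, seed and input digests.

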