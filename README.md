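# sitstand

Posture classification and sedentary bout patterns from hip-worn
accelerometers in children.

## The problem

Sedentary behaviour is defined by posture (sitting/lying) as well as by low
energy expenditure, but the most widely deployed measurement device in
child cohorts — a hip-worn ActiGraph accelerometer — is conventionally
scored with a movement cut-point (a minute is "sedentary" when its vertical
counts fall below 100 counts per minute). Movement cut-points cannot see
posture: quiet standing looks sedentary and fidgety sitting looks active,
so bout-pattern variables (bout durations, breaks, the power-law exponent
of the bout distribution) derived from counts agree poorly with a
thigh-worn inclinometer (activPAL), the posture reference.

`sitstand` implements an end-to-end pipeline that recovers
inclinometer-grade posture information from the hip sensor's raw signal:

1. **IO** — ActiGraph raw 30 Hz CSV, ActiGraph 60-s counts CSV and
   activPAL events exports are read and written losslessly.
2. **Pre-processing** — raw data are block-mean downsampled to 10 Hz and
   cut into 10-s epochs; inclinometer events are expanded to per-second
   labels and aggregated to 10-s epochs (an epoch is sitting when ≥ 6 of
   its 10 seconds are sitting).
3. **Non-wear** — the Choi algorithm on 60-s counts (90-min zero window,
   2-min spike tolerance, 30-min zero flanks).
4. **Classifier** — a convolutional feature extractor over each 10-s
   window of triaxial acceleration feeds a bidirectional LSTM across a
   sequence of epochs; a softmax emits the per-epoch sitting probability,
   and the label is SIT iff p(sit) > 0.5. The network is implemented in
   the package (im2col convolutions, backpropagation through time, Adam)
   and trains on a CPU in minutes at the default sizes.
5. **Bout variables** — maximal runs of sitting epochs give six
   participant-season variables: total sedentary min/day, breaks/day, time
   in bouts ≥ 30 min, mean bout duration, usual bout duration (the
   duration-weighted median: the bout length at which 50% of sitting time
   is accumulated), and the power-law exponent α with continuous MLE
   `α̂ = 1 + n / Σ ln(xᵢ/xmin)`.
6. **Evaluation** — per-participant-season confusion metrics (balanced
   accuracy = (sensitivity + specificity)/2), sit-to-stand transition
   pairing within a 1-min lag tolerance, and participant-level agreement
   (bias, MAE, MAPE, Spearman ρ, Lin's concordance
   `CCC = 2s_xy / (s_x² + s_y² + (x̄ − ȳ)²)`).

Because no public dataset pairs the two devices, the package ships a
synthetic generator (`sim_config()`, `make_study()`) that emulates a
simulated child-week: power-law sitting bouts (α ≈ 1.40, minimum 10 s),
lognormal upright bouts, the inclinometer's 10-s posture registration rule,
tilt- and movement-based 30 Hz hip acceleration, and counts integrated from
the dynamic signal. Every stage is deterministic under a seed.

## Worked example

Simulate six participants with one 1-h wear day each, train on three,
select the checkpoint on one, and evaluate on the remaining two:

```r
library(sitstand)

cfg <- sim_config(n_participants = 6, days_per_participant = 1,
                  day_wear_hours = 1, seed = 42)
make_study(cfg, "demo_study", valid_day_min = 30, min_valid_days = 1)

res <- run_pipeline(
  "demo_study", "demo_out",
  split = list(train = c("P01", "P02", "P03"), selection = "P04",
               test = c("P05", "P06")),
  mcfg = model_config(seed = 42),
  tcfg = train_config(max_epochs = 10, seed = 42),
  valid_day_min = 30, min_valid_days = 1)

print(res$epoch$summary, digits = 3)
#>                              metric  mean      sd n_defined
#> sensitivity             sensitivity 1.000 0.00000         2
#> specificity             specificity 0.991 0.00548         2
#> balanced_accuracy balanced_accuracy 0.995 0.00274         2
#> ppv                             ppv 0.996 0.00141         2
#> npv                             npv 1.000 0.00000         2
#> kappa                         kappa 0.993 0.00206         2

print(res$transitions$summary, digits = 3)
#>                  metric mean sd n_defined
#> sensitivity sensitivity    1  0         2
#> ppv                 ppv    1  0         2
```

Epoch-level balanced accuracy on the held-out participants is 0.995 and
every sit-to-stand transition is recovered within the 1-min window. The
participant-level agreement report shows the point of the method: the
classifier's bout variables track the inclinometer truth almost exactly,
while the 100 cpm comparator computed from the same recordings
underestimates sedentary time and badly distorts the bout metrics:

```r
print(res$agreement$model[, c("variable", "bias", "mae", "mape_pct", "ccc")], digits = 3)
#>             variable     bias     mae mape_pct   ccc
#> 1  total_sed_min_day  0.16667 0.16667    0.452 1.000
#> 2     breaks_per_day  0.00000 0.00000    0.000 1.000
#> 3 min_day_bouts_ge30  0.00000 0.00000    0.000 1.000
#> 4      mean_bout_min  0.01620 0.01620    0.452 1.000
#> 5     usual_bout_min  0.00000 0.00000    0.000 1.000
#> 6              alpha -0.00789 0.00789    0.520 0.865

print(res$agreement$cpm[, c("variable", "bias", "mae", "mape_pct", "ccc")], digits = 3)
#>             variable   bias   mae mape_pct     ccc
#> 1  total_sed_min_day -5.833 5.833    16.62  0.8288
#> 2     breaks_per_day -6.000 6.000    59.60  0.0000
#> 3 min_day_bouts_ge30 -0.417 0.417     2.33  0.9994
#> 4      mean_bout_min  4.354 4.354   116.21  0.2548
#> 5     usual_bout_min -0.500 0.500     2.18  0.9990
#> 6              alpha  0.158 0.158    10.37 -0.0018
```

## Command line

```sh
Rscript inst/cli/sitstand.R simulate --out study --participants 6 --days 1 --hours 1 --seed 42
Rscript inst/cli/sitstand.R nonwear --counts study/P01_day1_counts.csv --out wear.csv
Rscript inst/cli/sitstand.R all --study study --out out \
    --train P01,P02,P03 --selection P04 --test P05,P06 --seed 42
```
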