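# gazestate

Analysis pipeline for assessing learners' cognitive states — cognitive
overload, immersion, and distraction — from head-mounted-display
eye-tracking in VR learning sessions. The package is aimed at
researchers in educational VR and eye-tracking psychophysiology who
want the full chain from raw gaze vectors to subject-independent state
classification as tested, reusable code:

1. **I-VT event detection.** Angular velocity between consecutive unit
   gaze-direction vectors, `v = Δθ/Δt` with
   `Δθ = arccos(V_{i−1}·V_i)`; sample pairs below 30 °/s are fixation
   candidates, above 60 °/s saccade candidates, and events are
   validated by duration (fixations 100–500 ms, saccades 30–80 ms).
2. **AOI metrics.** Analytic ray–sphere/box intersection replaces the
   game-engine raycast; events are attributed to the majority-hit area
   of interest and four cumulative metrics (fixation duration/count,
   saccade duration/count) are accumulated as a time series.
3. **Synthetic study generator.** A calibrated simulator of the
   26-participant × 3-state within-subject design: moment-matched
   truncated-normal aggregates with participant random effects,
   monotone cumulative metric paths (7800 labelled steps, 2600 per
   class), planted-event gaze streams, and questionnaire scores
   (NASA-TLX, Flow State Scale, Distractibility, intrinsic/extraneous/
   germane load).
4. **Statistical battery.** One-way repeated-measures ANOVA
   (`F(2, 50)` at n = 26) with Mauchly sphericity test and
   Greenhouse–Geisser correction, partial eta squared, Bonferroni
   paired post hocs with pooled-SD Cohen's d
   (`d = |m1−m2| / sqrt((s1²+s2²)/2)`), and pooled Pearson
   correlations.
5. **Classifier.** Sliding-window (T = 10) sequence classification
   under leave-one-subject-out cross-validation: a from-scratch
   50-unit LSTM (dropout 0.2, batch norm, softmax head, Adam,
   early stopping) plus random-forest and gradient-boosted-tree
   baselines on identical folds, with train-only standardization and
   participant-grouped validation splits so no information leaks
   across subjects.

## Worked example

Detect events in a simulated noise-free stream and accumulate metrics:

```r
library(gazestate)

gs <- simulate_gaze_stream(duration_s = 5, seed = 3, fix_jitter_v = 0)
ev <- detect_gaze_events(gs$samples)
table(ev$kind)
#> fixation  saccade
#>       14       14
max(abs(ev$t_start - gs$ground_truth$t_start))
#> [1] 0
```

All 28 planted events are recovered with zero boundary error. Run the
statistical battery on a full simulated study:

```r
study <- simulate_study(simulation_spec(seed = 1))
bt <- run_stats_battery(study)
bt$anova[1, c("measure", "F", "df1", "df2", "eps_gg", "p_gg", "eta_p2")]
#>   measure           F     df1 df2   eps_gg  p_gg     eta_p2
#> 1 fixation_duration 18.0  2   50    0.887   4.35e-06 0.418
```

`F(2, 50)` is the within-subject test across the three states for 26
participants; `eps_gg` is the Greenhouse–Geisser epsilon applied to the
degrees of freedom, and `eta_p2` the partial eta squared. Classify
unseen participants:

```r
st <- simulate_study(simulation_spec(n_participants = 10, seed = 11))
w <- window_dataset(st$series, T = 10,
                    channels = c("t", "fixation_duration",
                                 "fixation_count", "saccade_duration",
                                 "saccade_count"))
res <- run_loso(w, model = "lstm",
                hp = hyperparams(max_epochs = 30, patience = 5, seed = 5))
res$summary[res$summary$metric == "accuracy", ]
#>   metric    mean   sd
#> 1 accuracy  84.1   15.3
```

Chance is 33.3%; shuffling the window labels drops accuracy to ~33%.

The numbered drivers under `analysis/` run these stages end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_detect_events.R 1
Rscript analysis/03_stats_battery.R 1
Rscript analysis/04_classify.R 1
```

## Method details

See the methods vignette,
`vignettes/cognitive-state-pipeline.Rmd`, for the model assumptions,
parameter defaults and units, the generator's calibration strategy,
and the design decisions behind the ambiguous corners (the 30–60 °/s
velocity band, count semantics, effect-size convention, feature-channel
configurations).
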