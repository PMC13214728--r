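---
title: "From gaze vectors to cognitive states: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gaze vectors to cognitive states: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: what each stage
computes, the assumptions behind it, the parameters that matter, and the
design choices that were genuinely open. The pipeline targets a common
experimental setup in VR learning research: participants wearing an
eye-tracking head-mounted display complete three learning sessions, each
engineered to induce one cognitive state — cognitive overload (label 0),
immersion (1), or distraction (2) — while 120 Hz gaze-direction vectors
are recorded, and each session ends with a battery of questionnaires.

# I-VT gaze-event detection

Head-mounted eye trackers report a unit gaze-direction vector $V_i$ with
a timestamp $t_i$. The angular difference between consecutive vectors is

$$\Delta\theta_i = \arccos\!\big(\mathrm{clamp}(V_{i-1}\cdot V_i,\,-1,\,1)\big),$$

and the angular velocity of the pair is $v_i = \Delta\theta_i / \Delta
t_i$ with $\Delta t_i = t_i - t_{i-1}$ computed from the actual
timestamps, never assumed to be the nominal 1/120 s — this keeps the
detector correct under dropped frames. The clamp matters: floating-point
dot products of collinear unit vectors routinely land a few ulps above
1, and an unclamped `acos` returns `NaN` exactly on the most common
input (a stationary gaze).

Velocity-threshold identification (I-VT) labels each consecutive sample
pair:

* **fixation** if $v < 30$ °/s,
* **saccade** if $v > 60$ °/s,
* **unclassified** otherwise.

The gap between the two gates is deliberate: HMD eye tracking is noisy
under head motion, and velocities between 30 and 60 °/s are ambiguous.
We treat them as carrying no label, and an unclassified pair terminates
any open event run. The alternative — assigning the band to one side —
would invent a third threshold the method does not define.

Maximal runs of identically-labelled pairs become candidate events, and
a duration gate then validates them: fixations must last 100–500 ms,
saccades 30–80 ms. Candidates outside their window are discarded
entirely rather than truncated or split; the duration criterion is a
validity filter (too-short runs are noise, too-long runs are likely
smooth pursuit or drift), not a segmentation rule. Recording gaps
(inter-sample interval above 3× the median) also terminate runs so that
blinks and dropouts never bridge two events into one.

On noise-free simulated streams the detector recovers every planted
event with zero boundary error; the property tests assert recovery with
boundary error at most one sample interval, the resolution limit of any
pair-based detector.

# AOI attribution and metric accumulation

In the VR scene, areas of interest (here: the organelles of an animal
cell) are spheres or axis-aligned boxes in meters, right-handed
coordinates. Instead of a game-engine physics raycast we intersect each
sample's gaze ray analytically — quadratic discriminant for spheres,
slab method for boxes — taking the nearest non-negative hit. A
point-sampling oracle along the ray cross-checks the geometry in the
test suite.

An event is attributed to the AOI hit by the **majority** of its
samples' rays (ties broken by the earliest hit within the event), or to
`none`. Four cumulative metrics are accumulated per AOI: fixation
duration, fixation count, saccade duration, saccade count. Each
completed event adds its full duration and increments its count by one
at its end time. A count could plausibly tick at both collision start
and end; we increment once per completed event, which keeps "count"
equal to the number of events — the semantics every downstream summary
assumes. Metrics are emitted on a fixed 10 Hz grid, so a 10-second
session yields ~100 records per AOI; per-session aggregates for
statistics are the final cumulative values.

# The synthetic study generator

The participant dataset the pipeline was designed around is not
publicly released, so the generator emulates its statistical structure:
26 participants × 3 states, a 100-step metric series per session (7800
labelled time steps, 2600 per class), and questionnaire scores. It is
an *aggregate-level* simulator: per-session aggregates are drawn from
normal distributions matching the published per-state means and SDs,
not from a cognitive mechanism — anything richer would be invention,
since only means and SDs are reported.

Three design choices deserve explanation:

* **Within-subject correlation.** Each participant receives one
  additive random effect per measure with SD equal to half the
  printed (marginal) SD; the within-session noise SD is scaled so the
  marginal SD still matches the target. Without this, repeated-measures
  ANOVA would be exercised on data with no subject-level structure.
  No covariances are published, so the 0.5 fraction is a conventional
  "moderate reliability" choice, configurable via `re_frac`.
* **Moment-matched truncation.** Questionnaire scales are bounded
  (NASA-TLX treated as 0–20, FSS 1–5, Distractibility 1–7, the
  cognitive-load subscales 0–10 — the instruments are described as
  21-, 5-, 7- and 11-point without anchors, so the anchors are
  configurable) and metrics are non-negative. Naive truncated-normal
  draws are biased upward when a target sits near a bound (extraneous
  load in immersion has mean 1.34 and SD 1.67 on a 0–10 scale; plain
  truncation at 0 would inflate the mean by ≈ 0.5). We therefore solve
  for the latent location whose *post-truncation* mean equals the
  target, keeping sample means calibrated to the printed tables within
  sampling error.
* **Monotone metric paths.** A session's cumulative series places the
  drawn number of events at uniform positions over the 100 steps, with
  random positive duration shares summing to the drawn aggregate. The
  series is therefore non-decreasing, as real cumulative metrics are,
  and the per-step increments — not just the final level — carry the
  state signal the classifier windows see.

The intrinsic-load scale can additionally load on the session's
standardized metric deviation (`il_coupling`, default 0.3), inducing
the positive IL–metric correlations a pooled session-level analysis
shows; the loading replaces part of the within-noise so the marginal SD
is preserved. All randomness flows from one integer seed through named
sub-streams (gaze, metrics, questionnaires), so identical
specifications reproduce byte-identical datasets.

What the generator does **not** emulate: head motion, blinks, pupil
dynamics, drift in calibration, non-normal questionnaire response
styles, or any temporal structure in state expression beyond the
monotone accumulation. Passing tests therefore demonstrate that the
pipeline's machinery is correct and calibrated to the published
summary statistics — not that it would achieve the same numbers on the
real recordings.

# The statistical battery

For each of the ten measures (four metrics, six scale scores) the
battery runs a one-way within-subject ANOVA: with $k = 3$ states and
$n = 26$ participants, $F$ has $(k-1, (k-1)(n-1)) = (2, 50)$ degrees of
freedom, and partial eta squared is
$\eta_p^2 = SS_{\text{state}} / (SS_{\text{state}} + SS_{\text{error}})$.
Mauchly's $W$ tests sphericity (it matches `stats::mauchly.test`
exactly in the test suite), and the Greenhouse–Geisser
$\hat\varepsilon$ — computed from the double-centered condition
covariance, bounded in $[1/(k-1), 1]$ — is applied to both degrees of
freedom. The GG-corrected p-value is always reported alongside the
uncorrected one rather than gated on the sphericity test: with $k = 3$
the correction is cheap and uniformly safer.

Post hoc comparisons are paired t-tests for the three state pairs with
Bonferroni correction ($p \times 3$, capped at 1). The effect size is
Cohen's d in the **root-mean-square-SD convention**:

$$d = \frac{|m_1 - m_2|}{\sqrt{(s_1^2 + s_2^2)/2}}.$$

This convention was chosen because it exactly reproduces the published
post hoc effect sizes from the published per-state means and SDs across
all 21 comparisons (to one unit in the last printed digit — the printed
inputs are themselves rounded). A paired-difference-SD convention does
not. The 95% CI on the signed standardized difference uses a normal
approximation, $d \pm 1.96\,\mathrm{se}$ with
$\mathrm{se}^2 = 2(1-r)/n + d^2/(2(n-1))$ where $r$ is the pair
correlation; CI methods for repeated-measures d are not standardized,
so these intervals are reported but not treated as reference values.

Pearson correlations between scales and metrics pool all participant ×
state observations (n = 78), matching the session-level analysis
convention; per-state correlation is available by filtering the input.
Under the null (no state effect, participant effects present) the
battery's F test holds its nominal size: 2000-replicate calibration
keeps the rejection rate at 5% ± 1.5%.

# Subject-independent classification

The classifier asks whether short windows of the metric series suffice
to identify the cognitive state of an *unseen* participant. The
pipeline is deliberately leakage-free:

1. Series are linearly interpolated to the longest length (identity on
   the default generator, where all sessions have 100 steps).
2. Stride-1 sliding windows of $T = 10$ consecutive steps are built
   *within* each session; the window label is the state at its final
   step, and a window never spans two sessions or participants.
3. Leave-one-subject-out: one fold per participant, test = that
   participant's windows.
4. Channel standardization is fit on the training fold only.
5. The LSTM's early-stopping validation split is grouped by
   participant, preserving the subject-aware principle inside training.

The network is a single 50-unit LSTM (tanh), dropout 0.2 on the final
hidden state, batch normalization, and a 3-unit softmax head, trained
with integer-label cross-entropy, Adam at 0.001, batch size 32, up to
100 epochs with patience-10 early stopping restoring the best
validation-loss parameters. No deep-learning framework is available to
this package, so forward and backward passes (truncated BPTT through
the full window, batch-norm and dropout included) are implemented in
vectorized base R; the backward pass is verified against numerical
differentiation in the test suite. Baselines — random forest and
gradient-boosted trees on flattened $T \times F$ vectors — consume the
exact same folds.

Two feature configurations exist. The default is the four cumulative
metrics. The *production* configuration adds the timestamp as a fifth
channel (input width 5, window default 10; the reference
architecture's stated input shape of 20 × 5 differs on window length,
which is why $T$ is a knob rather than a constant). The timestamp channel matters:
cumulative levels are ambiguous without it — a mid-session overload
window and a late-session immersion window can have similar levels —
and with it LOSO accuracy on 10-participant simulated studies is
roughly 60–85% across seeds, versus unstable 45–65% without. Analysis
and acceptance runs use the five-channel configuration.

Reported metrics per fold: accuracy, macro precision/recall/F1,
one-vs-rest macro-AUC from the softmax scores (rank-statistic
implementation, checked against pROC), mean cross-entropy, and the
confusion matrix; summaries are means with sample SDs ($n-1$) across
folds, plus class-wise averages across folds (macro weighting — the
alternative, pooling windows before averaging, weights participants by
window count and was rejected as less subject-fair).

# Problem sizes and numerical choices

The package's own study sizes: generator calibration and the
statistical battery run at the full 26 × 3 design; classification
analyses run at 10 participants with 30-epoch training, which keeps a
full LOSO sweep at a few minutes on one core while remaining far above
chance; the type-I calibration uses 2000 replicates. Tolerances:
velocity comparisons are exact (no smoothing is applied to gaze
vectors before velocity computation — whether the reference
implementation smoothed is unknown, and adding an undocumented filter
would change the detector's contract); ANOVA agreement with the
sum-of-squares oracle is asserted at 1e-8; calibration checks use 3
standard errors. Degenerate inputs are handled explicitly: zero-length
gaze vectors, non-increasing timestamps, non-positive intervals and
AOI sizes raise errors; zero-variance difference vectors in post hocs
are flagged degenerate with p = 1; zero-variance channels are centered
and flagged rather than divided by zero.

# Known limitations

* The generator is calibrated to summary statistics; it cannot validate
  claims about the real dataset's temporal microstructure, and
  classifier accuracies on synthetic data are not comparable to
  accuracies on real recordings.
* The 30–60 °/s band policy and the smoothing question are genuine
  unknowns of the reference method; both are documented knobs here.
* Cohen's d confidence intervals use a normal approximation and are not
  reference-grade.
* The LSTM is CPU-bound pure R; it is adequate for the study sizes here
  but not for large-scale hyperparameter search, which is out of scope.
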