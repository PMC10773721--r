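---
title: "Predicting next-day injury risk from training-load windows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting next-day injury risk from training-load windows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Overuse injuries in runners are strongly linked to how training load
accumulates and fluctuates, but the relationship is non-linear, lagged, and
highly individual. `injurisk` implements a prediction pipeline for the
*day approach* to load monitoring: each sample is the 7 days of 10 daily
load variables preceding a prediction day (session count, running volumes by
intensity zone, sprinting, strength and alternative training, and three
perceived 0–10 ratings), labelled by whether an injury occurred on the
prediction day. Injuries are rare (on the order of 1% of athlete-days), so
the whole pipeline is built around extreme class imbalance.

The model chain is:

1. **Per-athlete min–max normalization** (`normalize_per_athlete()`):
   `x~ = (x - x_min)/(x_max - x_min)` computed per athlete and variable over
   that athlete's full history, so that load *patterns* are comparable
   across athletes whose absolute volumes differ by factors of two or more.
   A variable that is constant for an athlete maps to 0 by convention.
2. **Windowing and padding** (`build_windows()`, `pad_window()`): 7×10
   window matrices, padded to 8×10. The extra row exists because the
   auto-encoder halves the spatial size twice (8 → 4 → 2) and mirrors it
   back (2 → 4 → 8); 7 is not divisible by 4. Edge padding (repeat the last
   day) is the default: it adds no artificial discontinuity to the angular
   or recurrence encodings, unlike a zero row. Zero padding is available.
3. **Time-series image encoding** (`encode_windows()`): each variable's
   8-step series becomes an 8×8 matrix; the 10 variables stack into an
   8×8×10 image. Four encodings are implemented from first principles:
   GASF/GADF (`cos(θi+θj)`, `sin(θi−θj)` after the arccos polar transform),
   the Markov transition field (Q = 5 uniform-width value bins over [0, 1],
   first-order transition probabilities expanded along time), and the binary
   recurrence plot (`1{||Sl − Sm|| < ε}`).
4. **Multiple resampling** (`multiple_resample()`): the three-step
   rebalancing described below, applied to flattened window features.
5. **Representation learning** (`dcae_fit()`): a symmetric convolutional
   auto-encoder compresses each image stack to 5 latent variables.
6. **Classification** (`dnn_fit()`): a 4×50 SELU network with a sigmoid
   output, trained with focal loss.
7. **Attribution** (`latent_variable_importance()`): Shapley values connect
   the 10 input variables to the 5 latents, and the latents to the
   classifier's risk output.

## The resampling procedure

Training directly on ~1% prevalence data lets the majority class dominate;
rebalancing is done in three steps, each with an exactly checkable count
contract (recorded in the provenance report):

* **Step 1 — balanced per-athlete sampling.** Every athlete with at least
  one injured and one uninjured window contributes exactly `k` windows of
  each class (drawn with replacement when fewer are available). This
  prevents the injured class from being dominated by a few high-risk
  athletes. `k` defaults to the ceiling of the mean injured-window count
  per retained athlete; only the step's balance, not `k` itself, is pinned
  by the procedure.
* **Step 2 — controlled unbalanced subsampling.** The balanced set is
  subsampled back to a fixed class geometry: `n_injured_target` injured
  windows (default 650) and `round(n_injured_target/ratio)` uninjured ones
  (default ratio 0.136, i.e. 650/0.136 → 4779). The default constants are
  treated as fixed plan parameters.
* **Step 3 — SMOTETomek.** Tomek links (mutual opposite-class nearest
  neighbours under Euclidean distance) are removed *from the majority class
  only*, cleaning the class boundary without ever discarding scarce injured
  samples; SMOTE then interpolates new minority samples
  `d_new = d + u·(d_n − d)`, `u ~ U[0,1)`, between each parent and one of
  its `k = 5` nearest minority neighbours until the classes balance. All
  synthetic points are convex combinations of real minority points, and
  each synthetic sample's parents and `u` are recorded.

Resampling operates on the flattened 8×10 window features and the image
encoding is applied *afterwards*, so synthetic samples are valid time
series and every encoded image preserves encoding invariants (e.g. MTF
row-stochasticity). Interpolating in image space could violate those
invariants, which is why the order is fixed this way.

One interpolation-direction subtlety: the conventional SMOTE step moves from
the parent *towards* the neighbour (`d + u(d_n − d)`). A literal variant
that reflects away from the neighbour (`d + u(d − d_n)`) is provided as
`smote_literal = TRUE` for comparison, but the conventional direction is the
default because only it guarantees convexity.

## Model architectures and losses

The **DCAE** is conv(3×3, 32) → avg-pool(2) → conv(3×3, 64) → avg-pool(2) →
dense → 5 linear latent units, mirrored by dense → 2×2×64 →
nearest-neighbour upsample → conv(3×3, 32) → upsample → conv(3×3, 10) with a
tanh output. Hidden layers use SELU activations with batch normalization
(applied to the affine output, before the activation) and dropout 0.1; the
bottleneck is linear so latent coordinates are unconstrained. Training
minimizes mean squared reconstruction error with adadelta (initial step 1.0,
accumulation decay 0.95), 100 epochs, batch 512 by default. GASF/GADF images
already live in [−1, 1]; MTF/RP images in [0, 1] are affinely mapped to
[−1, 1] (`rescale = TRUE`) to match the tanh output range. Average pooling
was chosen over max pooling as the mirror image of nearest-neighbour
upsampling (the two are adjoint maps up to a constant), keeping the
encoder/decoder truly symmetric; the exact per-layer widths are
configuration-exposed (`autoencoder_spec()`), as is the dropout rate.

The **classifier** takes the 5 latents (standardized with training
moments), passes them through four 50-unit SELU layers with batch
normalization and dropout, and emits a sigmoid probability. Its loss is the
**focal loss**

\[ L = \begin{cases} -\alpha (1-\hat y)^{\gamma} \log \hat y & y = 1 \\
 -(1-\alpha)\, \hat y^{\gamma} \log(1-\hat y) & y = 0 \end{cases} \]

with `alpha = 1 − n_minority/n_total` computed from the *unresampled*
training windows (≈0.986 at 533 injured of 39 722, the scale the defaults
assume) and `gamma = 3.5`. At `gamma = 0`, `alpha = 0.5` the loss reduces
exactly to half the binary cross-entropy, which is tested numerically.

Both networks are trained by a small in-package engine (im2col
convolutions, sparse-matrix pooling/upsampling, analytic batch-norm
gradients, adadelta) whose gradients are verified against central finite
differences in the test suite. Training is exactly reproducible given a
seed; inference (encoding, prediction) is deterministic, with dropout off
and batch normalization using running moments.

## Evaluation protocol

`holdout_protocol()` fixes an athlete-level split (no athlete on both
sides), then repeats the fit five times by default with consistent
parameters: resample the training windows, fit DCAE and classifier on the
resampled set, validate on the *entire* training set (internal validity),
and test on the held-out athletes (external validity). Metrics are
sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, their geometric mean,
and the rank AUC (Mann–Whitney with mid-rank ties, identical to the
trapezoidal ROC area, and invariant to monotone score transforms — both
properties are tested). The decision threshold for confusion-based metrics
is 0.5 and configuration-exposed, since threshold choice is not part of the
method itself.

Across-repeat subset selection in Step 2 is driven by a golden-ratio
additive low-discrepancy sequence with a per-repeat offset instead of fresh
pseudo-random draws. The intent is to spread the fitting subsets evenly
across the balanced pool so that repeat-to-repeat variation reflects the
method, not sampling clumps; a seeded pseudo-random mode remains available
by omitting the offset. Run-level comparisons (e.g. between encodings) use
Welch's heteroscedastic ANOVA (`stats::oneway.test`) and Games–Howell
post-hoc pairwise comparisons (Welch-type standard errors with
studentized-range p-values), reporting mean differences; both are
cross-checked against an independent reference implementation in the tests.

## Attribution

Shapley values are estimated by marginalizing absent features over a
background set: exact subset enumeration when there are at most 10 players,
permutation sampling otherwise. For the variable-per-latent surface, the 10
image *channels* act as players (a channel is present or absent as a
block), which is equivalent to summing pixel-level contributions within a
channel and keeps the enumeration exact at 2^10 coalitions. For the
classifier surface the 5 latents are the players (2^5 coalitions).
Importance is the mean of absolute per-sample contributions (signed
contributions of opposite direction would otherwise cancel; a literal
signed-mean mode exists), and latent importances are normalized to relative
importances summing to 1. Local accuracy (contributions plus base value
reconstruct the model output), the dummy-feature axiom, and symmetry are
all property-tested.

## The synthetic cohort generator

`generate_cohort()` produces training logs whose structure matches what the
pipeline assumes: ~74 athletes (64 train / 10 test at full scale),
athlete-specific baseline volumes (log-normal around 9 km/day),
rest-day probabilities, weekly periodization with occasional high-volume
blocks, ten load variables with ratings bounded on 0–10, and rare injuries.
Injury on day *t* follows a logistic model on two standardized summaries of
the preceding week — cumulative 7-day training volume (total km plus
alternative-training hours) and the acute day-over-day jump — plus an
athlete-level susceptibility intercept. The default coefficients (1.5 per
SD of cumulative volume, 1.0 per SD of acute jump) encode a cohort whose
injuries are strongly load-driven: training volume is the dominant planted
predictor, which is exactly the regime the attribution analysis is supposed
to surface. The intercept is calibrated by bisection against the realized
uniform draws, so the achieved prevalence matches the target (default 1.3%)
up to count quantization for any seed; an unreachable target raises an
error naming the achievable prevalence.

What the generator does *not* emulate: multi-day injury spells (each injury
is an independent day-level event), missing training days, seasonality
beyond the 4-week cycle, measurement error in perceived ratings correlated
with fatigue, and any injury mechanism outside the planted load pathway.
Consequently, a passing end-to-end test demonstrates that the pipeline can
recover a load-driven risk signal through the full
normalize–encode–resample–compress–classify chain — not that it attains any
particular performance on real training logs.

## Numerical choices and degenerate inputs

* arccos inputs are clamped to [0, 1] to absorb floating error; genuinely
  out-of-range values raise an error (they indicate missing normalization).
* MTF bins are uniform on [0, 1] (right-closed at 1); bins never visited
  leave all-zero transition rows rather than being imputed uniform.
  The transition matrix orientation is `P(next bin | current bin)`, with a
  transpose switch because the two conventions are easy to confuse.
* The recurrence threshold defaults to ε = 0.2 × the maximum pairwise state
  distance in the window (shared across channels, floored at machine
  epsilon so constant series come out fully recurrent); the embedding is
  dimension 1, delay 1 — an 8-step series leaves no room for longer
  embeddings, though both are configurable.
* Probabilities entering the focal loss are clamped at 1e−7 from both ends.
* Nearest-neighbour ties (Tomek, SMOTE) break to the smallest index,
  making resampling fully deterministic given its seed.
* Normalization state can be reused on new data from the same athletes;
  values outside the stored range are clamped to [0, 1]. Test athletes are
  normalized from their own history by default — the alternative (reusing
  train-time state) applies only when the same athletes appear on both
  sides, which the athlete-disjoint protocol forbids.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run scaled-down versions of
the full protocol, chosen to exercise every stage at sizes a laptop handles
comfortably: a 64-athlete × 200-day cohort for the resampling-count
contracts (step-2 geometry 650/4779 as at full scale), and a 30-athlete ×
200-day cohort (24 train / 6 test, ~5 800 windows, step-2 geometry
150/1103) with 30 auto-encoder epochs and 60 classifier epochs for the
end-to-end planted-signal recovery. At these sizes the planted-signal GASF
pipeline reaches a held-out AUC well above 0.8 while the signal-free
control stays near chance. On the attribution side the two top-ranked
latents are both volume-linked, with the total-km-dominated latent
statistically tied at the top of the classifier's relative importances — a
caveat worth knowing: because perceived exertion in the generator tracks
relative daily volume closely, volume information spreads across several
channels and more than one latent can absorb it, so the single
"volume latent ranks strictly first" reading is knife-edged at this scale.

## Known limitations

* The engine is CPU-bound, pure R; it is sized for 8×8 image stacks and
  thousands of samples, not for large-scale hyperparameter searches.
* Latent dimension 5 is fixed by the downstream attribution design;
  nothing prevents other values, but the reporting surfaces assume 5.
* The classifier threshold 0.5 is a convention; with heavily resampled
  training data the validation-set operating point can sit far from the
  Gmean-optimal threshold.
* Attribution cost grows as 2^players × samples × background; the defaults
  (50 samples, 10 background rows) keep exact enumeration tractable and are
  the knobs to raise for smoother heatmaps.
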