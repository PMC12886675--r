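---
title: "Models and methods behind multisense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind multisense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`multisense` models the data-analysis stack of a multiplexed
electrochemical microneedle patch that samples dermal interstitial fluid
(ISF) and reads six biomarkers in parallel: glucose, uric acid (UA) and
cholesterol by chronoamperometry, and Na+, K+ and pH by open-circuit
potentiometry. Because the underlying animal dataset is not public, the
package pairs every analysis component with a synthetic generator whose
statistical structure matches what the analysis assumes, so that the whole
chain — simulate, sense, calibrate, train, evaluate, explain — is testable
end to end. This vignette explains the models, the defaults, and the
choices made where the design was genuinely open.

## Sensor forward models

Amperometric channels follow the linear chronoamperometric law
`i = i0 + S * C` in current density (uA cm-2), with sensitivities taken
from the device's reported calibrations: 0.1122 uA cm-2 mM-1 (glucose),
0.001395 uA cm-2 uM-1 (UA) and 0.1637 uA cm-2 mM-1 (cholesterol), over
linear ranges 0-20 mM, 0-1000 uM and 0-10 mM. Ion channels follow the
Nernstian decade law `E = E0 + S * log10(C / C_ref)` with near-Nernstian
slopes of 52.87 mV/decade (Na+, 5-160 mM) and 58.46 mV/decade (K+, 1-32
mM); the pH channel is linear at 57.61 mV per pH unit over pH 3-8. Three
conventions had to be fixed here:

* **Sign of the pH response.** Only the magnitude of the pH slope is
  reported; we adopt `E = E0 - 57.61 * pH` (potential falls as pH rises,
  the usual polyaniline behaviour). The calibration fitter reports the raw
  signed slope; the figure of merit is its magnitude.
* **Decade anchor.** The decade law needs a reference concentration; we
  default to `C_ref` = 1 mM. The choice only shifts the fitted intercept,
  never the slope.
* **Units.** All sensitivities are per cm² of electrode, so the twin works
  entirely in current density and never needs an electrode area.

Noise is additive, Gaussian and homoscedastic per channel. The baseline
noise SDs are free parameters (they are not reported for the device); the
amperometric defaults are fixed by inverting the detection-limit formula
`LOD = 3.3 * sigma / S` at the reported LODs (0.39 mM, 2.7 uM, 0.52 mM),
which makes the twin's figures of merit land on the device's. The
chronoamperometric settling transient is modelled as a single exponential
(30 s settle budget): only the steady state feeds calibration, so a
mechanistic Cottrell treatment would add parameters without changing any
downstream quantity. Interference is an additive cross-term model
`delta = sum_j alpha_j * C_j`; the default coefficients are sized so that
the standard ISF interferent panel (ascorbic acid, UA, lactate, urea, and
ion cross-talk) produces relative drifts within the 6% the device reports.
The 120-min stability scenario uses a default baseline drift of -0.04% of
the initial signal per minute, which keeps signal retention above the 88%
reported threshold; both are documented scenario parameters, not claims
about any particular device unit.

## Calibration and figures of merit

Calibration is ordinary least squares of readout on the regressor —
concentration for amperometric channels, `log10(C / C_ref)` for ions, pH
for the pH channel. The reported `r` is the Pearson correlation of the
points (the convention the device's calibrations use), not R²; for a
simple linear fit the two coincide up to sign. Residual SD uses ddof = 2
(two fitted parameters); the relative standard deviation statistic uses
the sample SD (ddof = 1). Inversion is the exact algebraic inverse of the
fitted model; readouts mapping outside the calibrated range are flagged,
never silently clamped, because a silent clamp would bias downstream
concentration streams.

## The synthetic chronic cohort

The chronic study design is three diet groups — CON (standard chow), HFFD
(high-fat, high-fructose) and HFFSD (the same plus salt) — measured weekly
from week 0 (pre-diet baseline) to week 4. `cohort_config()` defaults to
the study's 3 animals per group; the ML experiment scales to 25 per group.
The generative model for a panel of animal *i* in group *g* at week *w* is

    x_igw = mu_0 + beta_g * w + a_i + e_igw

with baseline means `mu_0` inside the physiological ranges (glucose 5.5
mM, UA 295 uM, cholesterol 4.0 mM, Na+ 140 mM, K+ 4.2 mM, pH 7.1), a
per-animal random intercept `a_i` (SD = half the measurement SD,
reflecting correlated repeated measures on the same animal), and
measurement noise `e`. Glucose and cholesterol deviations share a latent
Gaussian factor with correlation 0.6 at both the animal and measurement
level, so the marginal glucose-cholesterol correlation equals the
configured value. Values are clipped to the sensor linear ranges with a
logged count, mirroring physical saturation rather than rejection
sampling.

The per-week effect rates `beta_g` are not reported anywhere, only their
qualitative pattern: both diets raise glucose, cholesterol and UA;
cholesterol separates control from diet, glucose separates the two diets,
and the salted diet additionally perturbs sodium and pH. The defaults
(HFFD: +1.5 mM glucose, +70 uM UA, +1.0 mM cholesterol per week; HFFSD:
+3.2, +100, +1.2, plus +4.0 mM Na+ and -0.12 pH per week; K+ carries no
effect) encode that pattern and are calibrated so the cohort is
near-separable: the exact Bayes classifier of the generative model,
evaluated by Monte Carlo on 600,000 draws, attains 0.99945 accuracy
(0.9986 on week 1, the hardest slice). That near-separability is a design
requirement of the default experiment, since the benchmark the CNN is held
to presupposes an almost noiseless class structure.

The **health degree** — the regression target — has no recorded recipe;
we construct it as a deterministic latent ramp `s_max * w / W` per group
(`s_max` = 0 / 0.7 / 1.0 for CON / HFFD / HFFSD) plus N(0, 0.02) label
noise, clipped to [0, 1]. This is a stand-in that makes
parameter-recovery testing possible; it is not a claim about how any real
label was produced.

Because all three groups coincide at week 0 by construction, week-0
windows are excluded from the default classification experiment
(`include_baseline_week = FALSE`): no classifier can beat 1/3 accuracy on
an exchangeable slice, and including it would cap overall accuracy near
0.87 regardless of model quality.

## Acute interventions

The hyperglycemia challenge (HG) drives glucose along a gamma-like pulse
`(t/tp)^4 * exp(4 * (1 - t/tp))` that is zero until onset (5 min), peaks
at 20 min and decays to under 3% of the peak within the 30-min return
window; only the peak time and the qualitative pulse-and-return shape are
anchored to the reported trajectories, so a smooth unimodal pulse is the
least-committal choice. The hyperuricemia challenge (HUA) holds UA at
160.2 uM for the first ~15 min, then rises logistically to a 1015 uM
plateau. The plateau slightly exceeds the UA channel's calibrated 1000 uM
top of range — the reported in-vivo level genuinely does — so the acute
simulator allows the challenged channel 10% headroom above its calibrated
range while all other channels remain range-clipped. The sham protocol
(NORM) is stationary noise about baseline on every channel.

## Feature windows and preprocessing

Each panel becomes `windows_per_panel = 5` model inputs: 6-channel × 60
sample windows at 1 Hz, each sample the channel's forward-model steady
state plus its sensor noise — one simulated minute of stabilized
recording per window, in raw signal units (current density or mV).
Standardization is Z-score with population SD, fitted **per fold on the
training windows only** and applied unchanged to validation windows; the
scaler carries a `fit_on = "train"` tag that the test suite asserts, so
any leakage of validation statistics into preprocessing is a test
failure, not a silent bias.

Cross-validation is stratified fivefold: within each class, units are
ordered by degree and dealt to folds in blocks of five with a seeded
random fold order per block, which balances both the class counts (within
one sample) and the degree distribution across folds. The dealt unit is
the *animal*, not the window: repeated measures of one animal are
correlated, and letting an animal straddle training and validation would
leak identity. A flag disables subject grouping for designs without
repeated measures.

## The multi-task CNN

The model is a hard-parameter-sharing network: five 1-D convolutional
layers over time (channels 16-32-32-64-64, kernel 3, stride 1, "same"
padding, ReLU), global average pooling, then two task branches — a linear
3-way classification head and a linear scalar regression head. The joint
loss is `cross-entropy + lambda * MSE` with `lambda = 1`; the MSE is
computed on the degree label standardized by training statistics, so the
two losses start on comparable scales, and the regression output is
mapped back and clipped to [0, 1] only at report time (clipping inside
the loss would zero gradients at the boundaries). Exact layer widths for
the original network are not available; this is the minimal design
honouring the five-shared-conv-layers constraint, and every choice is a
config field.

Training is Adam (initial lr 1e-3, batch 32) for 80 epochs with a cosine
learning-rate decay to 5% of the initial rate, decoupled weight decay
(1e-4), label smoothing (0.1), and a data augmentation specific to this
setting: a random per-channel DC offset (SD 0.1 in standardized units,
constant across the window) added to each training window. The
regularisation stack was motivated by a concrete failure mode, worth
recording. With plain constant-lr Adam the network drives the training
cross-entropy to ~1e-4 — it memorises the training animals — while a
quadratic discriminant fitted to the same folds beats it by one to two
accuracy points, and the held-out errors are entire animals whose panels
sit at their group means. That is a boundary misplaced by animal-level
idiosyncrasies of the training draw. The offset augmentation attacks the
cause directly: it makes the learned boundary invariant to exactly the
per-subject baseline shifts that the subject-grouped cross-validation
tests generalisation over, and is standard practice for wearable-sensor
models where inter-subject and inter-sensor baselines vary. Label
smoothing keeps the cross-entropy gradient alive after the training set
is fitted, and the cosine schedule settles the boundary late in
training. All of these are `mtl_config()` fields. The whole network —
im2col convolutions as BLAS matrix products, backward pass, AdamW — is
implemented in base R inside the package, and the backward pass is
verified against central finite differences to below 1e-5 relative error
in the test suite.

The engine is deterministic given the config seed on a fixed BLAS: all
stochastic elements (initialisation, batch order) flow from seeded
streams, and identical runs produce bit-identical histories.

## Baselines, metrics and interpretability

The classical-ML comparison harness runs KNN, SVM (RBF), a decision tree,
a random forest and XGBoost on the flattened per-channel window means,
under the identical folds and train-only standardization. These are
standard toolkit calls by design — the harness exists for comparison, not
as a contribution. KNN reports classification only.

Evaluation metrics are implemented from their definitions: accuracy and
macro precision/recall/F1 from the confusion matrix (0/0 treated as 0),
one-vs-rest precision-recall curves with tie groups pooled at each
distinct threshold and average precision as the step integral, and
R²/RMSE/MAE for regression.

The t-SNE used for cluster-structure inspection is the exact algorithm
(per-point precision calibrated to the target perplexity by bisection,
early exaggeration ×4 for 100 iterations, momentum 0.5→0.8 with gain
adaptation, learning rate 200), which is practical because embedded sets
here are hundreds of points. Only the mean silhouette width on the 2-D
coordinates is ever asserted — coordinate geometry is not a stable
contract of t-SNE. Perplexity defaults to 30 and should be kept below a
third of the sample count; tests use perplexities commensurate with their
cluster sizes, since a perplexity far below the cluster size fragments
clusters and deflates the silhouette for reasons unrelated to class
structure.

Feature attribution is exact Shapley by coalition enumeration: with six
channels there are only 64 coalitions, so the axioms (efficiency, dummy,
symmetry, linearity) hold to numerical precision rather than
approximately — the package treats the exact enumeration as normative and
validates its permutation-sampling estimator against it within 3 standard
errors. The attribution unit is the whole channel (all 60 samples swapped
to baseline together); the baseline is the channel-wise training mean,
i.e. the zero window after standardization; and the classification head
is attributed on the predicted-class logit rather than the probability,
which avoids coupling attributions through the softmax. Under the default
cohort the classification-head ranking puts cholesterol and glucose on
top — a consistency check of the generator's effect pattern, not a claim
about any real animal.

## Problem sizes and runtime

The default experiment uses 25 animals per group × 4 post-baseline weeks
× 5 windows = 1,500 windows of 6 × 60 samples, chosen to give roughly 500
windows per group; fivefold training takes a few minutes on one core. The
test suite trains smaller cohorts (240 windows, 20-sample windows, 8-15
epochs) for the behavioural checks and reserves the full-scale run for
the headline-metric tests. Monte-Carlo checks (correlation recovery,
Bayes separability) use 10^3-10^5 draws.

## Known limitations

* The cohort generator is Gaussian with linear-in-week effects; real
  metabolic trajectories saturate, interact and skew. Passing tests show
  the analysis stack is correct under its stated assumptions, not that
  those assumptions describe rat physiology.
* The health degree is a constructed label; recovery of it demonstrates
  the regression plumbing, nothing more.
* Sensor noise is white and homoscedastic; real electrochemical noise has
  1/f structure and drift correlated with temperature and motion. Drift
  and motion artifacts exist in the twin but default to off outside the
  dedicated scenarios.
* The CNN runs on one CPU core in base R; it is sized for this package's
  experiments, not for large-scale reuse.
* In-vivo recalibration (per-subject offsets) is supported but defaults
  to none; whether the original workflow used one-point on-body
  recalibration is unknown.
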