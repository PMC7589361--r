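---
title: "Lying-posture tracking from a single accelerometer: models, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lying-posture tracking from a single accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturetrack)
```

## The problem

A person lying still in bed holds one of four major postures: supine, prone,
left lateral or right lateral. A tri-axial accelerometer worn on the body
measures, to first order, the projection of gravity onto its three axes, so
each posture leaves a characteristic static signature in the sensor frame.
For a chest sensor the horizontal axis separates supine from prone (means
near +0.92 g and −0.78 g after unit normalization) and the lateral axis
separates the side postures (about ∓0.80 g); the vertical axis stays near
0 g in every lying posture. `posturetrack` classifies *episodes* — maximal
contiguous recordings of one subject holding one posture — into the four
postures, from a single sensor at any of nine wearing sites (chest, left and
right thigh, ankle, arm, wrist).

Two model families are provided:

* **Ensemble of bagged decision trees** on 48 time-domain features computed
  over sliding windows and averaged into one meta-feature vector per
  episode.
* **AdaLSTM**, a bidirectional LSTM over the raw tri-axial sequence with
  three fully connected layers and a softmax, trained with Adam under a
  decaying learning-rate schedule against a length-weighted cross-entropy.

Both are evaluated by leave-one-subject-out (LOSO) cross-validation with
macro metrics and a coefficient-of-variation (CoV) consistency analysis.

## Data model and preprocessing

An episode holds a subject id, body site, posture label, sampling rate
(25–30 Hz in the datasets this emulates) and an N×3 matrix of accelerations
in g units. Preprocessing operations:

* `normalize_episode()` rescales all axes by one scalar so the median
  per-sample vector magnitude is 1 g. The normalization is deliberately a
  *scalar* gain correction: per-axis standardization would destroy the
  gravity-orientation signal that every model here relies on. It corrects
  subject/device gain differences (including sensors recording on a raw
  ±10-style analog scale, also reachable via `read_dataset(scale = 10)`).
* `segment_by_labels()` cuts a continuous labeled recording at every label
  change; null labels are discarded.
* `resegment_episode()` cuts long constant-posture recordings (e.g. 300 s
  activity-protocol runs) into fixed 20 s chunks; a trailing remainder
  shorter than one chunk is dropped. With 300 s at 25 Hz and 20 s chunks
  this is exact: 7500 samples → 15 × 500.
* `integrate_datasets()` merges a short-episode dataset with a resegmented,
  per-label seeded subsample of a long-episode dataset, restricted to the
  shared sites. The subsample is a uniform draw without replacement under
  the caller's seed, making integration reproducible.

Axis-role convention: axes are stored as raw x/y/z; the package treats x as
lateral, y as vertical, z as horizontal (the chest convention above). A
dataset-level JSON config (`read_config()`) can carry a different
`axis_roles` mapping, a unit `scale`, and the label vocabulary. The
vocabulary's *order* matters: it is the deterministic tie-break for every
argmax/vote in the package.

## The 48 time-domain features

For each of the three axes: peak amplitude (max − mean), median, mean, max,
min, variance, standard deviation, RMS, peak-to-peak, zero-crossing rate,
entropy, skewness, kurtosis, range and mean absolute deviation (45
features); plus three scalars: mean vector magnitude, total energy
Σ(s_x²+s_y²+s_z²), and the maximum elevation angle
atan2(s_z, √(s_x²+s_y²)) (48 total, names `f01_amp_x` … `f48_mad_z`).

Numerical choices where the textbook definitions are ambiguous or
degenerate:

* **ZCR**: the literal "fraction of exactly-zero samples" definition is
  degenerate on continuous signals; the default is the standard
  sign-change rate (changes/N), with the literal rate behind
  `literal_zcr = TRUE`.
* **Entropy**: defined on a 16-bin histogram of the window's own range,
  natural log, with 0·log 0 ≡ 0; a constant window has entropy 0 and the
  uniform histogram attains log 16.
* **Variance/SD**: sample variance (N−1 divisor) and its square root.
* **Skewness/kurtosis**: population third/fourth central moment over σ³/σ⁴
  (σ the sample SD); defined as **0 when σ = 0**, because constant windows
  occur in zero-noise simulation.
* **Peak-to-peak and range** are the same quantity under two names; both
  are kept so the feature vector indexes stay stable.

The window length is the *minimum episode length in the training set*
(recomputed inside each LOSO fold from training episodes only, to avoid
leakage), with 50% overlap. A test episode shorter than the window is used
whole as a single window.

Each episode's windows are averaged component-wise into one
48-dimensional meta-feature vector — the classifier input.

## The tree ensemble

`train_ensemble()` grows (by default) 100 trees, each on a bootstrap
resample of the training episodes with a random feature subset drawn once
per tree (default ⌊√48⌋ = 7). Trees split on one-hot-coded class indicators
with a sum-of-squared-error criterion, unlimited depth, minimum leaf 1.
Prediction is majority vote; ties go to the earlier label in the
vocabulary.

Feature importance follows the "MSE decrease" convention: every split's
impurity decrease is credited to its feature, per-tree sums are divided by
that tree's branch-node count, and trees are averaged. The SSE criterion on
one-hot indicators is what makes this MSE-style definition well-defined for
classification. On gravity-signature data the episode-mean and median/min/
max features of the informative axes dominate the ranking, matching the
physical picture.

Two linear baselines operate on the 3 per-axis episode means only: an LDA
classifier (hand-implemented, with a ridge option on the within-class
covariance — required because zero-noise data is exactly singular) and a
one-vs-rest squared-hinge linear SVM.

## AdaLSTM

The sequence model consumes raw (normalized) tri-axial episodes. One LSTM
(10 hidden units) scans forward, one backward; padded positions carry the
state through unchanged, so the forward terminal state is the state at the
last *true* sample and the backward terminal state covers the sequence from
its end to its first sample. The two are concatenated (20 values) and
passed through fully connected layers of sizes 10, 10 and K with tanh
between them, then a softmax.

The loss is the length-weighted cross-entropy
−Σ_i Σ_j m_i y_ij log ŷ_ij, where m_i is the length of sequence i: longer
episodes cost proportionally more to misclassify. It is an unnormalized sum
(the per-epoch trace also records the mean for readability); natural log;
true-class probabilities are clamped at 1e-12.

Training: episodes are sorted by length and cut into mini-batches of 27 (to
shorten padding), batch order reshuffled each epoch; Adam with β₁ = 0.9,
β₂ = 0.99 (the squared-gradient decay), initial learning rate 0.01, up to
100 epochs. The decay schedule is not uniquely determined by convention, so
the package's default is piecewise ×0.5 every 20 epochs; setting
`lr_schedule = "constant"` reproduces the fixed-learning-rate LSTM
baseline. The recurrence uses full LSTM gating (input/forget/output gates
and a memory cell): the directional wiring is the contract, and a gateless
simple recurrence would forfeit exactly the long-sequence stability the
architecture is chosen for. Forward pass, backpropagation through time and
Adam are implemented in plain R; the analytic gradients are verified
against numerical differentiation to 1e-4 relative error in the test
suite. Everything is deterministic for a fixed config seed on a single
thread.

## Evaluation

All metrics derive from the l×l confusion matrix via per-class one-vs-rest
counts:

* **accuracy** — the *macro average of one-vs-rest accuracies*
  mean_i (TP_i+TN_i)/(TP_i+TN_i+FP_i+FN_i). This is what the formula
  convention used here prescribes; note it is not the pooled trace/total
  accuracy, which is exposed separately as `pooled_accuracy()`.
* **macro precision / recall**, with zero-denominator classes contributing
  0 under a warning;
* **F1** — harmonic mean of macro precision and macro recall;
* **balanced accuracy** — (Σ TP_i/P_i + Σ TN_i/N_i)/(2l);
* **CoV** — sd/mean of a metric over LOSO folds (sample sd, n−1).

`run_loso()` holds out each subject in turn, refits the requested model on
the remaining subjects (window length, LDA ridge, etc. all recomputed
within the fold) and aggregates. Folds whose training split collapses to a
single class are skipped with a warning. `kruskal_compare()` wraps the
Kruskal–Wallis rank test for comparing two groups of CoV values; the
package reports p-values and takes no inferential stance.

## The synthetic generator

Real benchmark recordings are not redistributable, so the package ships a
seeded simulator used by every test:

* a **per-(site, posture) gravity direction table**
  (`default_orientation_model()`). The chest row is calibrated to the
  characteristic values above (+0.92/−0.78 g horizontal, −0.80 g lateral);
  the other eight sites are this package's own plausible limb-geometry
  choices — documented assumptions, not measurements — and all 36 entries
  are overridable. Distal sites (arms/wrists) are given intrinsically
  closer directions across postures.
* a **per-(subject, site) mounting rotation** (Rodrigues rotation about a
  random axis, angle ~ N(0, 10°)), drawn once and applied to all of that
  subject's episodes — the modeled source of inter-subject variability.
* **measurement jitter**: i.i.d. Gaussian, default sd 0.05 g.
* **movement bursts**: raised-cosine excursions of 1–3 s in a random
  direction (default peak 0.5 g) at a default 2/min, multiplied ×3 at the
  arms and ×4 at the wrists — emulating nocturnal limb repositioning, the
  known cause of degraded wrist/arm classification. Bursts are deliberately
  not a biomechanical limb model; they are sufficient to reproduce the
  qualitative proximal ≫ distal site ordering.
* durations ~ N(12.2 s, 3.6 s) truncated at 1 s, 30 Hz, matching the
  short-episode protocol the generator emulates; `duration_fixed_s = 300`
  at 25 Hz gives the long-recording style (exactly 7500 samples).

What a green test on this generator establishes: that the full pipeline —
features, ensemble, AdaLSTM, LOSO harness — recovers planted
posture-orientation structure under realistic noise magnitudes, and that
site quality orderings propagate through both model families. What it does
not establish: performance on real recordings, whose noise (respiration,
posture drift, label errors, unit bugs) the generator does not imitate;
the published benchmark numbers are therefore *not* reproduced here, only
the arithmetic checkpoints and qualitative orderings.

Noise defaults were chosen once, before the acceptance thresholds were
evaluated, as values a wearable-sensing practitioner would call realistic
(0.05 g jitter ≈ a consumer MEMS accelerometer at rest; 10° mounting
variation; a few repositioning events per minute at distal sites), and are
not revisited.

## Worked example

```{r example, eval = FALSE}
library(posturetrack)

synth <- simulate_dataset(simulation_config(n_subjects = 12,
                                            sites = "chest", seed = 1))
posture_axis_summary(synth$dataset, "chest")

res <- run_loso(synth$dataset, "ensemble", "chest", seed = 1)
res$summary
#              metric   mean      sd     cov
#   1          accuracy 0.9896 0.03608 0.03646
#   2         precision 0.9688 0.10825 0.11175
#   3            recall 0.9792 0.07217 0.07370
#   4                f1 0.9735 0.09185 0.09435
#   5 balanced_accuracy 0.9861 0.04811 0.04879
res$confusion
#           predicted
#   truth    supine prone left right
#     supine     12     0    0     0
#     prone       0    12    0     0
#     left        0     0   11     1
#     right       0     0    0    12
```

## Known limitations

* The simulator has no posture transitions, respiration or heart-beat
  components; episodes are statically held postures.
* The tree grower is exact but O(n² p) per node in the worst case; it is
  sized for episode-level datasets (hundreds of rows), not sample-level
  ones.
* The AdaLSTM is CPU-only plain R; it is fast enough for the intended
  episode counts (seconds per fold) but not for large corpora.
* LDA on exactly collinear (zero-noise) features requires the ridge
  option; the LOSO harness passes `reg = 1e-6` for robustness.
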