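---
title: "carehar: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{carehar: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`carehar` recognises complex nurse-care activities, and identifies the
performing nurse, from a single tri-axial accelerometer. This vignette is the
package's own account of the science: the model and its assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, the numerical choices, and the places where the design was
genuinely open.

## The recognition problem and its assumptions

The unit of classification is a *segment*: a contiguous window of
acceleration samples carrying exactly one activity label and one user label.
The method assumes (i) a single body-worn tri-axial accelerometer with a
roughly constant but unknown mounting orientation per user, (ii) activity
information concentrated below about 20 Hz (the band of human motion), and
(iii) strong class imbalance and intra-class variability as the defining
obstacles, rather than sensor scarcity. Everything else — augmentation,
orientation-robust features, the multi-branch network, fusion — exists to
attack (iii) under constraint (i).

## Pre-processing

Timestamps are converted to numeric seconds, rows are stably sorted, and
samples are merged with labels either by segment id or by closed time
intervals (`start <= t <= finish`; a sample exactly on a boundary belongs to
the interval). Samples covered by no label are dropped and counted.
Overlapping intervals are an error by default with a `first-wins` option,
since the data model gives no ground to prefer either silently.

Missing acceleration cells are mean-imputed per column. Inside the
evaluation harness the means are computed *within each user's own samples*
(`impute_segments()`): a global file mean would let a held-out subject's
values leak into training statistics, which the no-leakage audit in the test
suite explicitly forbids. For 60 Hz data, segments are cut into
non-overlapping 60-sample windows (1 s), the window the evaluation protocol
fixes; the 4 Hz chest-pocket dialect keeps whole segments because no window
size is defined for it.

## Augmentation

Five label-preserving operators perturb a segment without changing its
length or labels. Their Gaussian parameters are nowhere fixed by the
protocol, so the package adopts values usual in the wearable-augmentation
literature, all configurable: jitter `N(0, 0.03 * sd(signal))`, scaling
`N(1, 0.1)`, warp knots `N(1, 0.2)` with curve complexity `phi = 4`
(i.e. 6 knots). Choices the definitions leave open:

* One warp curve is shared across the three axes (magnitude and time
  warping), preserving inter-axis geometry.
* The time-warp's cumulative-average curve is rescaled to span exactly
  `[0, m - 1]` before linear resampling, so the output length equals the
  input length (required by the fixed-length network input) and the
  endpoints are pinned. Non-monotone curves (possible when a knot draw goes
  negative) are redrawn up to 10 times, then error.
* Operator pairs such as `"mw+tw"` compose left to right.
* `balance_augment()` cycles each class's originals through the configured
  operator until every class holds exactly `A` segments; originals are kept
  untouched and augmented segments record operator and parent segment. The
  enlargement that performed best in validation is 3x the majority count
  (`run_config(augment = list(factor = 3))`, the default factor); the test
  suite mostly balances to the majority count (`factor = 1`) to stay inside
  its compute budget — the direction of the effect, not its ceiling, is what
  the tests establish.

Rotation draws a uniform axis (normalised from `U[-1,1]^3`) and an angle
from `U[-pi, pi]`; because the matrix is orthogonal the per-sample magnitude
channel is preserved to machine precision, which the tests assert — this is
exactly why magnitude statistics are orientation-robust features.

## Filtering and features

Each axis passes a width-5 running median (edge windows shrink) and then an
order-3 Butterworth low-pass at 20 Hz, applied forward and backward for zero
phase. Two numerical points deserve note:

* The digital filter is designed by the bilinear transform with prewarping;
  its true response at frequency `f` is
  `1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^6)` per pass. Near Nyquist
  this differs hugely from the analog textbook curve: at 25 Hz with
  `fs = 60` the two-pass amplitude gain is 0.0099, not 0.208. The tests
  check attenuation against this exact closed form (and against the analog
  formula far below Nyquist, where the two coincide).
* At 4 Hz sampling the 20 Hz cutoff exceeds Nyquist and the filter stage is
  mathematically void; it is skipped with a warning rather than applied
  meaninglessly.

The 13 intermediate channels are the filtered axes, the magnitude, per-axis
displacement and velocity (single and double cumulative trapezoids with
`dt = 1/fs`, starting at 0), and per-axis orientation angles
`arctan(a / sqrt(b^2 + c^2))`, with the all-zero sample mapped to angle 0
and a zero denominator to `±pi/2`. Nine statistics per channel give 117
named features. Definitions the name alone does not fix: MAD is the
unscaled `median(|x - median(x)|)`; IQR uses linear-interpolation (type-7)
quantiles; energy is the *mean* of squares so it is window-length-invariant.

**MSUM.** All strict interior relative extrema are located (a flat plateau
counts once, at its first index; extrema then alternate strictly). Each
extremum is connected to its second-successive opposite-type extremum —
three positions ahead in the alternating sequence — and MSUM is the mean
absolute value gap over all such lines; series with no complete line score
0. Pairing is independent per extremum (it does not restart after a matched
pair); "distance" is the vertical value gap, since the defining sum
subtracts line endpoint values directly. A brute-force oracle that walks the
extremum list literally confirms the implementation exactly on 1000 random
series in the test suite.

## Feature selection

Correlation pruning computes pairwise Pearson correlations and scans
upper-triangle pairs in canonical column order, dropping the later column of
any still-alive pair with `|r| > 0.9` (the threshold is configurable; "highly
correlated" is not quantified anywhere). Zero-variance columns correlate
with nothing, survive, and are flagged. The procedure is deterministic and
idempotent.

Ranking uses mean decrease in impurity from a random forest fitted once on
the full (pruned) table — refitting per fold is available through the
harness, which always fits selection inside the training fold. Rows are
canonically ordered by segment uid first so the ranking cannot depend on row
permutation. The saturation cut evaluates cross-validated accuracy for the
top-k features over a grid (every integer to 60, then strides of 5) and
returns the smallest k within `epsilon = 0.005` of the curve maximum,
computed in plain double arithmetic. For activity recognition the evaluator
is leave-one-user-out; for nurse identification it is a stratified 5-fold,
because a user's identity cannot be predicted after holding out that user.

## Models, fusion, evaluation

The stacked CNN gives each configured channel (defaults: three acceleration
axes and three angles — the channels that proved discriminative) its own
sub-model: conv(32 filters, kernel 16) → batch-norm → ReLU → maxpool(2),
then conv(16, 16) → batch-norm → ReLU → maxpool(2); flattened branch outputs
are concatenated into dropout(0.25) and softmax. The ingredient list fixes
no layer order; conv → BN → ReLU → pool is the standard choice taken here.
A `branch_mode` switch provides the two-branch (acceleration / angle) and
single-branch ("traditional CNN" baseline) wirings. Training: Adam at
lr 0.001, batch 32, categorical cross-entropy, at most 500 epochs, early
stopping when validation accuracy stalls for 100 epochs, best weights
restored. The evaluation protocol defines no inner split, so a stratified
20% of the training segments is carved per fit, seeded. The whole network
(im2col convolutions, batch-norm, pooling, dropout, Adam) is implemented in
vectorized base R inside this package — the runtime environment has no deep
learning framework — and its backward pass is verified against finite
differences in the tests. Desk-scale runs in the tests and the acceptance
script cap epochs at 60 (patience 25); on the separable synthetic worlds the
network converges long before that, and the caps are a compute-budget
scaling, not a tuning device.

The companion model is a CART random forest (Gini splits, bootstrap
bagging, `mtry = floor(sqrt(p))`, 500 trees by default; unstated by the
protocol, so standard values) on the 117 statistical features — the full
intermediate-set statistics, whereas the CNN sees raw axes + angles only.
It is implemented in compiled code in this package because the environment
ships no random-forest library. Probabilities are averaged leaf class
proportions; importance is normalised MDI.

Fusion takes `S(y) = sum_i beta_i P_i(y)` with `beta = (2, 1)` for
(CNN, forest) — the empirically best weights — unnormalised, since argmax is
scale-invariant; ties break to the lowest class index. Evaluation is
leave-one-subject-out for activities: each fold refits augmentation,
features, selection and both models on the remaining users only, and the
report's provenance records every uid that entered each stage so leakage is
checkable, not just claimed. Precision/recall/F1 are macro-averaged
(averaging scheme unstated; macro is the conservative choice under
imbalance), per-class ratios with empty denominators count as 0, and pooled
accuracy equals the confusion-matrix trace over the total.

## The synthetic world

`generate_dataset()` emulates the structure the method exploits, not
biomechanics. Each activity is a two-harmonic sinusoid motif (base
frequencies 0.6, 1.3, 2.0, ... Hz — the cadence range of care motions —
with per-axis amplitudes of 0.2–0.5 g) riding on a 1 g gravity-like offset;
each user has a fixed sensor tilt (axis-angle rotation, 0.35 rad steps);
segments add per-segment phase, ±10% amplitude and ±5% frequency jitter,
Gaussian sensor noise (default SD 0.05 g, a realistic consumer-MEMS figure),
and optional missingness. Within a class the motif draw is keyed by the
replicate index only, so corresponding segments of two users differ exactly
by tilt and noise — making "rotation preserves magnitude" testable
end-to-end. Default size: 4 users x 4 activities x 12 segments of 2–4 s at
60 Hz, chosen so a full leave-one-user-out run of the fused ensemble
finishes in about a minute on one CPU.

What a green test does establish: the pipeline's stages compose correctly,
are deterministic under seeds, never leak held-out users, recover
far-above-chance structure when it exists, sit at chance under permuted
labels, and time-warp balancing raises minority recall on a 10:1 imbalanced
world. What it does not establish: performance on real nurse recordings —
real data have non-stationary motifs, label noise, transient artefacts and
inter-activity similarity that sinusoid mixtures do not reproduce.

## Known limitations

* The CNN path pads/truncates segments to a fixed input length (default 60
  samples, edge-padded); very long segments contribute only their first
  window unless windowing is applied upstream.
* Pure-R training is single-threaded and desk-scale; hundreds of epochs on
  thousands of segments would call for a compiled backend.
* Nurse identification cannot use leave-one-subject-out by construction;
  `stratified_cv()` is the package's protocol for it, which measures
  within-known-user generalisation rather than open-set identification.
* The saturation evaluator defaults to the forest path for speed; selecting
  features against the full fused ensemble would be faithful but an order
  of magnitude slower, and is available by passing a custom evaluator.
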