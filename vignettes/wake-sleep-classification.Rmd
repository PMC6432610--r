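---
title: "Methods: video-based actigraphy and wake/sleep classification"
author: "vactig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based actigraphy and wake/sleep classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vactig)
```

## The problem

Infant sleep is usually scored from polysomnography (PSG), which requires
electrodes on a small and fragile subject. Body movement alone already
carries a lot of the wake/sleep signal: infants move often and vigorously
while awake and only sparsely during sleep. A ceiling-mounted infrared
camera can measure that movement without any body contact. `vactig`
implements the full chain from grayscale frames to a per-epoch wake/sleep
decision, together with a synthetic data generator so the chain can be
validated end-to-end without access to clinical recordings.

Throughout, the scoring unit is the standard 30-s epoch, wake is the
positive class, stages N1/N2/N3/R are collapsed into a single sleep class,
and unable-to-score (`U`) epochs are excluded from model fitting and all
metrics.

## Motion estimation

`estimate_motion_rs()` is a recursive-search block matcher. The frame is
tiled into `block_size` × `block_size` blocks (default 16 px; edge blocks
are cropped to the image and their cost normalized per remaining pixel).
For the transition from frame $t$ to $t+1$, each block considers a small
candidate set of integer displacement vectors:

* the zero vector;
* spatial predictors — the vectors currently assigned to the neighbouring
  blocks in the grid;
* the temporal predictor — the same block's vector in the previous
  transition;
* the best of those candidates perturbed by pseudo-random updates with
  components in $\{-2,\dots,2\}$ (3 draws by default), clipped to
  `search_bound` (default 8 px).

The matching cost is the *mean-subtracted* sum of absolute differences per
valid pixel: each patch has its own mean intensity removed before
differencing, so a uniform illumination change between frames moves no
block. A non-zero candidate wins only if it beats the zero-vector cost by
more than `noise_threshold` (default 1 intensity unit/pixel); this
zero-vector bias keeps the field silent under sensor noise, which matters
because the downstream activity count treats *any* non-zero vector as
movement.

Two design choices depart from a textbook single raster scan. Each
transition is scanned `passes` times (default 2) in alternating forward
and reverse raster order, and the spatial predictor set includes the
right/below neighbours as well as left/above. A single cold-start forward
pass can only propagate candidate vectors rightward and downward; the
alternating pass lets a good vector found anywhere in the grid reach every
block within the same transition, which is what makes single-frame-pair
estimation reliable. With the default smooth-textured test imagery the
estimator recovers global integer translations on essentially all interior
blocks and agrees with an exhaustive full-search oracle.

The per-frame activity count (`motion_field_to_actigraphy()`) is the
number of blocks with a non-zero vector — a deliberately crude but robust
quantity on the same scale for every recording made with the same
geometry. `frame_difference_actigraphy()` is a cheap baseline (count of
pixels changing by more than a threshold) retained for sanity checks; it
is *not* illumination-invariant.

## Epoch features

**mACT** is the mean activity count over the epoch's 300 frame transitions
(30 s at 10 Hz). A binary variant (fraction of frames with any movement)
is available via `mact_binary = TRUE`; the mean-count variant is the
default because it preserves movement intensity, and the two differ only
in how they weight long vigorous bursts.

**pSLP** targets the known failure mode of activity counts: *motionless
wake*. An infant that is awake but briefly still produces sleep-like mACT;
but such epochs tend to sit close in time to movement bursts. For each
recording, epochs whose mACT exceeds the recording's 95th percentile
(linear interpolation between order statistics, strict comparison) are
marked high-activity. For epoch $i$, $d_i$ is the distance in whole epochs
to the nearest high-activity epoch and $u_i = \ln(1 + d_i)$; pSLP is the
centered moving average of $u$ with half-width
$h = \mathrm{round}(10 \cdot 60 / (2 \cdot 30)) = 10$ epochs, i.e. a
21-epoch (10.5-min) window, truncated at the recording edges. Small pSLP
means "near a burst", hence wake-like. Choices worth making explicit:

* distance is measured in epochs, not seconds, and the log uses a $+1$
  offset so high-activity epochs themselves map to 0. Any monotone variant
  would give an equivalent classifier up to rescaling;
* the log is applied before smoothing (smoothing a heavy-tailed distance
  first would let single long gaps dominate the window);
* if a recording has no epoch above its 95th percentile — possible only
  for pathologically constant signals — pSLP is the constant
  $\ln(1+n)$ and the recording is flagged degenerate.

Both features are Min–Max normalized to $[0,1]$ *within each recording*
(constant vectors map to zero and are flagged). Per-recording
normalization removes between-subject scale differences (camera distance,
infant size) and, because it never pools statistics across recordings,
makes leave-one-subject-out evaluation leak-free by construction. Trailing
partial epochs are discarded; `U` epochs keep their feature values but are
excluded downstream.

## The classifier

`fit_lda()` fits Gaussian class conditionals with a shared covariance:
class means are per-class averages and

$$\Sigma = \frac{(n_w - 1) S_w + (n_s - 1) S_s}{n_w + n_s - 2},$$

the bias-corrected pooled covariance. The priors are fixed at
$(0.5, 0.5)$ regardless of training frequencies: with roughly 28% wake the
empirical prior would push the boundary toward calling everything sleep,
and the deployment balance is unknown anyway. The wake posterior is
computed in log space; with shared $\Sigma$ the log-odds is the linear
function $w^\top x + b$ with $w = \Sigma^{-1}(\mu_w - \mu_s)$, so the
0.5-posterior boundary is the hyperplane Mahalanobis-equidistant from the
two means. `predict()` calls wake when the posterior is at least the
threshold (default 0.5); the tie goes to wake to keep the rule
deterministic and to favor sensitivity on the positive class.

If the pooled covariance is singular or has condition number above
$10^8$ — e.g. duplicated feature columns — a ridge of
`ridge_fraction` · trace$/d$ (default fraction $10^{-6}$, escalating
tenfold until well-posed) is added to the diagonal. On real 2-D feature
data the ridge never engages; it exists so degenerate synthetic inputs
fail soft rather than with a singular solve.

## Evaluation protocol

`loocv()` holds out one subject per fold, fits on the pooled epochs of the
others, and scores the held-out subject at the fixed 0.5 threshold (the
per-subject operating point is *not* re-tuned per fold). Reported are:

* per-subject confusion cells, precision / sensitivity / specificity /
  accuracy / Cohen's kappa, and AUC;
* the mean ± SD of each metric across subjects — the headline
  aggregation — with undefined metrics (zero denominators) excluded and
  counted rather than silently zeroed;
* pooled confusion counts and pooled ROC over all test epochs. Pooled and
  per-subject-averaged numbers answer different questions and are never
  mixed.

Cohen's kappa is used alongside accuracy because the class balance is
skewed; $\kappa = (p_o - p_e)/(1 - p_e)$ with the usual two-rater chance
agreement. The ROC sweeps thresholds over the unique scores plus
sentinels; its trapezoidal AUC equals the tie-corrected pairwise
probability, which the tests verify against an $O(n^2)$ enumeration. The
Mann–Whitney U screen (`mann_whitney_u()`, a thin wrapper over
`stats::wilcox.test`) uses the exact permutation distribution for
combined samples up to 20 without ties and the tie- and
continuity-corrected normal approximation otherwise.

## The synthetic cohort generator

`sim_config()` defaults describe a laboratory-style cohort: 10 infants,
recording lengths drawn from $N(70, 26^2)$ minutes (truncated at 20), a
28% wake target, and 0.7% unable-to-score epochs. Its purpose is to
reproduce the *statistical structure* that makes this classification
problem what it is, at the activity-count level rather than
biomechanically:

* **Consolidated bouts.** Wake and sleep alternate in lognormal bouts
  (sleep mean 20 min, wake mean ≈ 7.8 min via the wake-fraction target,
  sdlog 0.6, minimum one epoch). Recordings are windows sampled from a
  longer stationary bout sequence, so the realized wake share fluctuates
  around the target without start-of-recording bias. Sleep has a sticky
  REM/NREM Markov substructure (stationary REM share 0.4, mean REM run
  10 epochs), with N1/N2/N3 assigned per NREM run.
* **Wake movement.** Within a wake bout, a frame-level burst/quiet Markov
  chain (on 0.02 / off 0.05 per frame) emits Poisson counts at 8
  blocks/frame in bursts and 0.2 between them. Most wake bouts (probability
  0.8) additionally contain a *motionless stretch* of 3–6 epochs at a
  uniformly random position, which emits exactly zero — the motionless-wake
  phenomenon pSLP exists for. Roughly a quarter of wake epochs end up with
  little or no movement, so an activity-count feature alone misses a
  substantial minority of wake, as it does on real recordings.
* **Sleep movement.** Sparse short events (rate 0.5/epoch in REM,
  0.15 in NREM; ~0.5 s, small amplitude) plus an occasional vigorous jerk
  at wake-like intensity (~2 s; probability 0.08 per REM epoch, 0.03 per
  NREM epoch). The jerks give sleep a high-mACT tail, so the wake and
  sleep feature distributions overlap instead of separating cleanly.
* **Rendering.** `render_frames()` draws a textured ellipse on a noisy
  dark background (default 80 × 64 px for speed); positive-activity
  transitions translate the ellipse by a logged integer step (≤ 3 px),
  with the texture riding in blob-local coordinates so the content
  actually moves. The log provides ground truth for closed-loop tests of
  the block matcher.

What the generator does **not** model — and what passing tests therefore
do not show about real data: camera placement and perspective changes,
occlusions, parental interference, out-of-bed periods, illumination
drift beyond a uniform offset, and any biomechanically realistic movement
shape. The generator's movement rates are calibrated to qualitative
structure (burstiness, overlap, REM > NREM), not to measured infant
statistics; its manifest says so.

## Numerical and formatting choices

* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7) with a strict `>` for the high-activity mask;
  on a constant recording the mask is empty.
* All indices are 0-based and intervals half-open in file formats
  (`epoch_index`, `frame_index`); epoch $i$ covers transitions
  $[300 i, 300 (i+1))$.
* Report CSVs print numerics through a fixed `%.10g` format, so reruns
  with the same configuration and seed are byte-identical.
* Every stochastic step (the matcher's random updates, all simulation)
  takes an explicit integer seed and restores the caller's RNG state;
  cohort subjects use sub-seeds derived deterministically from the cohort
  seed, kept below $2^{31}$.
* Undefined metrics are `NA` with a flag, never silently 0; kappa's
  $p_e = 1$ corner returns 0 with a degeneracy flag.

## Problem sizes in the test suite

The suite favors many small, exactly-checkable cases: motion tests run on
96 × 128 frames (48 blocks), oracle comparisons use up to 1,000 random
confusion matrices and 200 random burst masks, classifier recovery uses
10,000 points per class, and the end-to-end qualitative checks run 20
seeded replicates of the default 10-subject cohort (~1,400 epochs each),
which keeps the whole suite under a minute on one CPU while still
exercising every pipeline stage at full default parameters.

## Known limitations

* The recursive-search matcher is designed for reproducibility and
  robustness, not bit-compatibility with any particular published motion
  estimator; on low-texture imagery its zero-vector bias can under-count
  slow small movements.
* mACT is geometry-dependent (blocks/frame); cross-camera comparability
  relies entirely on the per-recording normalization.
* pSLP degrades when a recording's high-activity epochs are not
  concentrated in wake (e.g. heavy parental interference), and near
  recording edges where the smoothing window is truncated.
* The LDA assumes shared-covariance Gaussian classes; the 2-D normalized
  features are bounded, so the model is a pragmatic linear scorer rather
  than a literal generative truth.
* With ~10 subjects, per-subject mean ± SD has wide sampling error; the
  pooled numbers are tighter but conflate subjects.
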