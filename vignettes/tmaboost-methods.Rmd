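---
title: "Methods: weakly supervised TMA analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised TMA analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmaboost)
```

## The pipeline and its assumptions

`tmaboost` models the slide-to-decision chain for immunostained tissue
microarrays. A TMA slide is a multiresolution pyramid `{I_m}` in which
level `m` is a factor-2 downsample of level `m − 1` (exact 2×2 mean
pooling here, with replicate padding so `dims_m = ceiling(dims_0 / 2^m)`
holds for odd sizes). The chain is:

1. **Core detection** on a low-magnification level — the smallest level
   whose largest dimension fits a 2048 px budget, a choice that scales
   with slide size since the method only needs cores to be a few dozen
   pixels wide for blob detection.
2. **Forward mapping** of each detected box to level 0 (multiply all four
   components by `2^ξ`, clip to image bounds).
3. **Tumorlike tile selection** at level 0: non-overlapping M×M tiles,
   a per-pixel 3-class probability map (0 background, 1 other tissue,
   2 tumorlike), an argmax class map with ties to the lowest class,
   suppression of non-tumor pixels to 0 (with an explicit boolean mask so
   "suppressed" is never confused with "dark tissue"), and qualification
   of tiles whose tumorlike pixel fraction strictly exceeds α.
4. **Backward mapping** to a medium level
   `l = round(log2(w0 · h0 · 10^(−2ρ)) / 2)`, clamped to the pyramid.
   With ρ = 3 a 1000×1000 px core maps to level 0 and each quadrupling of
   the pixel count raises the level by one. The printed form of this rule
   is typographically ambiguous; the adopted grouping is the one that
   yields medium-resolution levels for centimetre-scale cores at 20×
   scanning, and the result is rounded to the nearest level (the rule
   does not state a rounding) and clamped.
5. **Core classification**: a pluggable backend scores each medium-level
   tumor tile with a probability of treatment effectiveness; scores are
   aggregated to β and thresholded at δ = 0.5, ties deciding Effective.
6. **Evaluation**: confusion metrics and ROC/AUC at core level,
   Kaplan–Meier/log-rank and Cox proportional hazards on predicted
   groups.

Key parameters, with defaults: tile size M = 512 px (the conventional
patch size; pipeline runs on synthetic slides use M = 32 to match the
smaller cores), qualification and attention threshold α = 0.05, cascade
IoU ladder φ = {0.5, 0.6, 0.7} with η = 3 stages and trade-off λ = 1,
backward-mapping exponent ρ = 3, decision threshold δ = 0.5, evaluation
grid 1000 iterations, loss-stability bound ε = 0.003, F-measure bound
τ = 0.1.

## Weak supervision: boosting, focusing sampling, boosted augmentation

Pixel annotation is assumed sparse (on the order of 1% of training
cores). Three mechanisms make that workable:

- **Attention initialization.** A tile enters training with weight 1 iff
  its annotated-positive fraction ϖ reaches α, and weight 0 otherwise —
  tiles without usable annotation contribute nothing to the first round.
  The boundary is inclusive (ϖ = α qualifies).
- **Misclassification-driven reweighting.** After each round, any tile
  whose misclassified-pixel fraction reaches α gains a fixed increment χ.
  The increment is not specified anywhere authoritative; the default
  χ = 1 keeps weights readable as "1 + number of boosted rounds" and is
  configurable. The denominator of the fraction is the full tile area
  (matching the attention statistic); ignore-masked pixels are excluded
  from the numerator since they generate no prediction targets.
- **Focusing sampling.** Unlabeled pixels are marked in an ignore mask
  and excluded from losses and error fractions rather than treated as
  negatives. `masked_pixel_loss()` makes the exclusion testable by direct
  recomputation.

Boosted tiles (weight above their initial value) are expanded with 10
deterministic geometric variants — the phrase "rotation per 5° and 5
times and increment of 90°" is read as five small rotations
{+5°, …, +25°} plus the right angles {90°, 180°, 270°}, alternative
readings being configurable in the recipe — plus horizontal and vertical
flips. Each variant receives photometric jitter drawn uniformly within
contrast ± 20%, saturation ± 20%, brightness ± 12.5%; wider configured
ranges are clamped with a warning. Rotation is implemented as in-package
nearest-neighbour inverse mapping (not a library resampler) so that
pixels, label maps and ignore masks — which contain NA for unknown — are
transformed by the *identical* operator; this is what makes the
"masks follow pixels" invariant checkable exactly.

The final model after U rounds (default U = 3; no authoritative value
exists) is the last base model — sequential refinement of a single
segmentation model — rather than an ensemble vote. This was a genuinely
open design point; the sequential reading matches a workflow that
retrains one network with reweighted data, and the full model list is
retained on the fit object so a voting combiner can be layered on
without changing the training loop.

## Backends, and what is deliberately not inside

The deep networks of a production system (a cascade R-CNN detector, a
16-layer segmentation network, a modified Inception V3 classifier) enter
only as backend *contracts*: a detector backend maps a level image to
scored boxes, a segmenter maps a tile to a 3-class probability map, a
classifier maps a tile to an Effective probability. The shipped
reference backends are CPU-cheap: a classical blob detector
(threshold → connected components → area within [0.25, 4]× the median →
circularity `4πA/P² ≥ 0.6`, score = circularity, greedy NMS at IoU 0.3 —
the NMS threshold and 0.5 minimum score are package choices), a
color-threshold segmenter keyed to the DAB-brown stain axis, a
ground-truth oracle segmenter for tests, and a logistic regression on
per-tile color summaries (channel means/SDs, brown index,
kept-pixel fraction). Connected-component labelling and shape features
delegate to EBImage; survival fits delegate to the survival package;
ROC/AUC is implemented in-package and cross-checked against the
Mann–Whitney identity in the tests.

## Model selection and early stopping

Checkpoints are compared through the loss series ω and F-measure series ι
on the evaluation grid. Derivatives are forward differences with the
grid treated as unit-spaced — at this resolution a "derivative" is simply
the change per evaluation, which is the scale on which the bounds ε and τ
are stated. The "continuous period" required for stability is 3
consecutive evaluations by default (unstated in any source; configurable),
and derivatives are not smoothed before thresholding — smoothing would
trade detection latency for noise robustness and can be layered on by the
caller. The search window opens at the first stable-loss run, closes at
the end of the first stable-F run (early stop) or the final iteration,
and the best-F checkpoint inside wins, the largest iteration breaking
ties. If the loss never stabilizes the window opens at the first
evaluation and the result is flagged `loss_converged = FALSE` rather than
erroring, so monitoring dashboards can still display a selection.

## The synthetic generator: what it emulates and what it does not

`generate_slide()` emulates the data *shape* the pipeline assumes: a
jittered grid of circular stained cores (jitter capped at 10% of the core
spacing so cores never touch — the classical detector assumes separable
blobs, and a spec requesting overlapping geometry is rejected), each core
holding a band-limited noise blob of tumor texture occupying 25–60% of
the disc. The outcome label (Effective with probability 0.572, the
prevalence of the motivating cohort; 12 default slides give 720 cores)
shifts the mean DAB-brown intensity of the tumor region by
`effect_size × noise_sd` on top of (a) i.i.d. pixel noise of SD
`noise_sd = 0.05` and (b) a per-core staining intercept of SD
`0.5 × noise_sd` representing core-to-core staining heterogeneity. The
intercept scale is a generator design choice (no authoritative value
exists): it makes the per-core feature distributions overlap so the
classification task is nontrivial but solvable at `effect_size = 2`, and
it is what limits the attainable AUC — per-pixel averaging alone would
make every effect size trivially separable.

What the generator does **not** emulate: nuclear/glandular morphology,
stain deconvolution artifacts, antibody-specific staining patterns,
tissue folds, pen marks, or out-of-focus regions. Passing end-to-end
tests therefore demonstrates that the pipeline's plumbing, thresholds and
statistics behave as specified — not that the reference backends would
classify clinical images; those need trained backends behind the same
contracts.

`generate_trace()` builds a piecewise-linear loss descent flattening
exactly at `plateau_start` (plus optional Gaussian noise), so the
stable-window detector can be checked against construction: the
recovered window start must land within one grid step of the plateau.
`generate_survival()` draws exponential event times with a group-1
hazard of `hazard_ratio` times baseline (default 0.18, a strongly
protective effect; baseline median 24 months), with optional uniform
censoring.

## Numerical choices and degenerate inputs

- Boxes are 0-based, top-left origin, half-open; all geometry tests are
  stated in that convention. Forward mapping then integer division by
  `2^ξ` recovers the input exactly when no clipping occurs.
- Class-map ties break toward the lowest class index; probability maps
  must sum to 1 within 1e-6 per pixel or the map is rejected.
- Tile qualification is strict (fraction > α); the literal mean-of-codes
  reading of the rule is available as `mode = "literal"` because the two
  readings genuinely differ (class codes 0/1/2 enter the literal sum).
- A core with no qualified tumor tiles is decided Invalid with β = 0 and
  flagged `no_tumor_tiles` — erroring would abort whole-slide runs on
  tumor-free cores, which are expected in practice.
- Suppressed pixels are written as 0 with a carried boolean mask; the
  suppression mask is downsampled by area-preserving block means and
  re-thresholded at 0.5, which conserves the masked fraction to within
  2% at the fetched level.
- Degenerate statistics error loudly: one-class ROC input, survival data
  with no events or one group, zero-variance Cox covariates, learners
  with no positively weighted annotated pixels ("no supervised signal").

## Problem sizes used by the tests and the acceptance script

Synthetic slides use 64 px cores on a 6×10 grid (level-0 ≈ 1056×672,
3 levels) with 32 px tiles; unit tests shrink to 2×3 grids of 32 px
cores. The end-to-end checks run five replicates of 12 slides (720 cores
each, 66/34 train/test split); survival power and size use 200 seeded
replicates of 50 subjects per arm; the Cox recovery uses 500 per arm.
These sizes were fixed once as the package's desk-scale study condition;
they keep a full acceptance run in the minutes range on a single CPU.

## Known limitations

- The cascade orchestrator fixes composition, per-stage relabeling and
  NMS, but no trainable stage models ship with the package; the classical
  detector carries end-to-end runs.
- The reference logistic backend sees only first-order color summaries;
  it cannot exploit spatial texture beyond what the generator encodes in
  the brown channel.
- `backward_level()` assumes the factor-2 pyramid; non-dyadic level
  ratios are out of scope.
- Patient-level aggregation of multiple cores is not modelled; the
  survival module takes one record per subject as given.
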