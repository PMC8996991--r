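# tmaboost

Weakly supervised treatment-effect prediction from immunostained tissue
microarray (TMA) whole-slide images.

## The problem

Anti-angiogenic therapy (bevacizumab) benefits only a subset of ovarian
cancer patients, and no routine biomarker directs patient selection.
Immunostained TMA slides — grids of circular 2 mm tissue cores, one per
patient sample, scanned as gigapixel multiresolution images — carry a
visual signal of the treatment outcome in the tumor regions of each core.
Exploiting it requires a pipeline that (i) finds every core at low
magnification, (ii) isolates the tumorlike tissue of each core at full
magnification with almost no pixel-level annotation, and (iii) classifies
each core as treatment-*Effective* or *Invalid* from its tumor appearance
at medium magnification. `tmaboost` implements that pipeline at desk
scale, with the deep networks of a production system replaced by pluggable
backends and seeded synthetic TMA slides standing in for clinical data.

## What is inside

- **Pyramid model** — levels `{I_m}`, `m = 0..M-1`, with `dims_m =
  ceiling(dims_0 / 2^m)`; forward mapping multiplies a box detected at
  level ξ by `2^ξ`; backward mapping picks the medium level
  `l = log2(w0 · h0 · 10^(-2ρ)) / 2` (ρ = 3) for tumor-feature fetch.
- **Core detection** — a classical backend (thresholding, connected
  components, circularity ≥ 0.6) plus a cascade orchestrator composing
  per-stage box regressors Ψ_ϑ and classifiers under strictly increasing
  IoU thresholds φ = {0.5, 0.6, 0.7} (η = 3, λ = 1).
- **Tumor tile selection** — M×M tiles, per-pixel 3-class probability maps
  (background / others / tumorlike) from a pluggable segmenter, argmax
  class map κ, suppression of κ ≤ 1 pixels, and qualification of tiles
  whose tumorlike fraction exceeds α = 0.05.
- **Boosted weak supervision** — instance weights `w_j = 1` iff the
  annotated-positive fraction ϖ ≥ α; after each of U rounds, `w_j += χ`
  for tiles with misclassified fraction ≥ α; boosted tiles gain 10
  geometric variants (5°-step rotations to 25°, right angles, both flips)
  with seeded photometric jitter (contrast/saturation ± 20%, brightness
  ± 12.5%); unlabeled pixels are ignored, never negatives.
- **Effect prediction** — per-tile Effective probabilities aggregated to
  β_d (mean by default) and thresholded at δ = 0.5.
- **Model selection** — first/second finite derivatives of the loss and
  F-measure series on a 1000-iteration evaluation grid; the search window
  starts where the loss derivatives stay in [−ε, ε] (ε = 0.003), ends at
  the F-measure early stop (τ = 0.1) or the last iteration, and the
  best-F checkpoint wins, later iterations breaking ties.
- **Evaluation** — confusion metrics, ROC/AUC, Kaplan–Meier + log-rank,
  Cox proportional hazards (via the survival package).
- **Synthetic TMA generator** — seeded slides (default 6 × 10 cores, 57.2%
  Effective) whose tumor-region DAB-brown intensity shifts with the
  outcome by `effect_size` noise-SD units, plus training-trace and
  survival-record generators.

## Worked example

```r
library(tmaboost)

# three synthetic slides, detection -> tile selection -> prediction
res <- run_synthetic_experiment(n_slides = 3, seed = 42)
res$recall                 # 1        (detection recall, IoU 0.5)
round(res$auc, 3)          # 0.993    (test-split AUC on core outcomes)
lapply(res$metrics, round, 2)
#> $accuracy  0.95   $precision 0.95   $recall 0.98   $f_measure 0.96

# derivative-based checkpoint selection on a training trace
tr <- generate_trace(num_iters = 20000, plateau_start = 5000,
                     noise_sd = 1e-4, seed = 42)
select_checkpoint(tr)
#> <selection_result: window [5000, 7000], i* = 5000, early stop>

# survival comparison of predicted groups
surv <- generate_survival(50, hazard_ratio = 0.18, seed = 42)
km_logrank(surv)$p         # 2.5e-11
cox_ph(surv)
#>   term    hr  lower upper       p
#>  group 0.234  0.149 0.369 3.5e-10
```

The detection recall says every generated core was found at IoU ≥ 0.5;
the AUC/accuracy row scores held-out cores on their simulated outcome;
the selection result shows the stable-loss window opening at the
constructed plateau (iteration 5000) and the early stop two evaluations
later; the Cox row recovers a hazard ratio close to the generating 0.18,
i.e. predicted-Effective subjects progress at roughly one fifth the rate.

A thin CLI covering `simulate`, `detect`, `model-select` and `evaluate`
ships in `inst/cli/tmaboost-cli.R`.

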