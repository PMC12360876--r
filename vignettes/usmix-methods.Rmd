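---
title: "Mixed-sample augmentation for ultrasound lesion segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-sample augmentation for ultrasound lesion segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usmix)
```

## The problem

Supervised lesion segmentation in ultrasound is annotation-starved:
delineating lesions frame by frame requires expert radiologists, while
unlabeled ultrasound images are abundant. Mixed-sample augmentation
sidesteps generative models (GANs, diffusion) by composing each new
training image directly from one *labeled* image/mask pair
`(I_L, T_L)` and one *unlabeled* image `I_U`, and assigning the result the
unmodified mask `T_L`. The composite is a valid supervised sample —
pseudolabeled by construction rather than by model prediction, so no
confidence filtering or teacher network is involved — and the unlabeled
pool contributes appearance diversity at essentially zero computational
cost.

## The operators

All arithmetic happens in the float `[0, 1]` intensity domain (8-bit PNGs
are normalized per file on load; working in floats avoids the overflow
ambiguity an integer-domain sum would create for PixMix2). With `T_L'`
denoting the Gaussian-smoothed soft mask:

* **PixMix** — `I_aug = α I_L + β I_U`. A global convex blend; `α` is the
  fraction of the labeled image's features retained. We constrain
  `α + β = 1`: the ablation protocol that selected the default operating
  point was run on the line `β = 1 − α`, and a convex combination
  guarantees the output stays in range. Default `α = 0.8, β = 0.2`, the
  configuration found most effective and stable in that ablation.
* **SegMix2** — `I_aug = (1 − T_L') I_U + T_L' I_L'` with
  `I_L' = γ I_L + (1 − γ) I_U`: the (optionally diluted) labeled lesion is
  transplanted onto the unlabeled background. `γ` has no canonical value;
  the default 0.5 is the symmetric, least-informative choice and is
  exposed as a parameter. The equation calls for the *smoothed* mask, so
  SegMix2 smooths with the same `sigma` as the lesion blends.
* **LesionBlend** — `I_aug = T_L' I_L + (1 − T_L') I_U`: the labeled
  lesion is kept and the background is replaced. (A natural-language
  reading of "replace the lesion area with new content" would suggest the
  opposite assignment; the equation is authoritative here, and its
  complement exists as LesionBlend2, so both readings are available.)
* **LesionBlend2** — `I_aug = (1 − T_L') I_L + T_L' I_U`: the exact
  complement. Pixelwise, `lesionblend + lesionblend2 = I_L + I_U`, an
  identity the test suite checks to 1e-12.
* **PixMix2** — `I_aug = I_L + I_U`. The raw sum lives in `[0, 2]`; by
  default it is min–max rescaled to `[0, 1]`, which preserves relative
  structure without saturating bright regions (a degenerate constant sum
  maps to all-zero); `pixmix2_overflow = "clip"` clamps instead.

The load-bearing property shared by all five is **label invariance**: the
returned mask is the *same object* as the input mask, so it is
bit-identical, and the tests quantify this over hundreds of seeded phantom
pairs. The operators contain no randomness; all stochasticity lives in
pairing and selection (the expansion protocol) under explicit seeds.

### Mask smoothing

`smooth_mask()` convolves the binary mask with a separable Gaussian,
truncated at `4σ` (radius at least 1 pixel), with symmetric (reflective)
boundary handling. The kernel is normalized, so constant masks are fixed
points and soft-mask values stay in `[0, 1]`. The original method
specifies Gaussian smoothing without parameters; we default to
`σ = 5` px at the 224×224 working resolution, which produces the visibly
feathered 10–20 px transition band the method's illustrations show, and we
keep `σ` configurable. The soft mask is used directly as continuous blend
weights — re-binarizing it would defeat its purpose of a seamless
transition. As `σ → 0` the kernel collapses onto its center pixel, so
SegMix2 with `γ = 1` and tiny `σ` degenerates to hard copy-paste; the
suite checks this limit at `σ = 0.01` to within one 8-bit quantization
step.

## Traditional baselines

For comparison experiments the package implements the standard trio, with
the parameterizations used in the comparison protocol: rotation with
angles uniform in 15–345° (near-identity rotations deliberately excluded),
translation up to ±20% of each axis, and zero-mean Gaussian noise with
variance uniform in 10–50 on the 0–255 intensity scale (converted to the
unit domain as `var/255²`), plus the horizontal-flip preprocessing step at
probability 0.5. Geometric transforms are applied jointly to image and
mask with the same draw; interpolation is bilinear for images and
nearest-neighbor (with re-binarization) for masks so no fractional mask
values are invented; out-of-frame pixels are zero-filled (the padding mode
of the original experiments is unstated; zero fill matches the black
margins typical of ultrasound stills). Translations are rounded to integer
pixels, half away from zero, so masks are shifted, never resampled.

## The expansion protocol

Low-annotation experiments sample a labeled subset — canonically 5%, 10%
or 20% of the full training set — and expand it back to the original size
with one strategy at a time:

1. `sample_subset()` sorts by `source_id` (order independence), then draws
   `round(fraction · n)` samples without replacement. Rounding is half-up,
   so 5% of a 414-case training set gives 21 (and 10% → 41, 20% → 83;
   expansion back to 414 generates 393/373/331 samples respectively).
   Sampling is unstratified; whether the original experiments stratified
   by lesion class is unknown.
2. `expand_dataset()` cycles labeled sources round-robin — a uniform draw
   would leave some of the few labeled samples underused — and draws
   unlabeled partners uniformly with replacement, redrawing any
   self-pairing (relevant when the pool is the remaining labeled images
   with masks hidden, the fallback when no separate pool is supplied).
   Per-sample seeds for the baselines and all pairings derive from the
   plan seed, and the pairing stream does not depend on the mixing
   weights, so `run_alpha_beta_sweep()` yields per-α datasets whose
   generated images differ by exactly `(α₁ − α₂)(I_L − I_U)`.

Every generated sample carries a provenance record (strategy, sources,
parameters as JSON, seed) written to `manifest.csv`;
`replay_sample()` regenerates any row bit-exactly, which the tests verify
at the PNG-byte level.

## Metrics

`confusion()`, `jaccard()` and `dice()` implement the standard
overlap statistics; `Dice = 2J/(1+J)` is asserted as an identity over
exhaustively enumerated small mask pairs. True negatives are counted for
completeness but enter no formula. When both masks are empty the overlap
is vacuously perfect; the functions return 1 with a warning and
`evaluate_masks()` flags the pair.

For the boundary metric, the printed max–min formula is the classical
(100th-percentile) Hausdorff distance, but the metric is conventionally
named and cited as HD95; `hd95()` therefore computes the 95th-percentile
variant by default — per direction, the 95th percentile of
boundary-point-to-set Euclidean distances, the two directions combined by
max — with `percentile = 100` reproducing the literal formula. Boundaries
are mask pixels minus their 4-connected erosion (frame border counts as
background), and the percentile uses the ceiling order statistic, so the
reported distance is always one actually attained between pixel centers
and reduces to the exact maximum for boundaries with ≤ 20 points.
Distances are in pixel units; no physical spacing is applied. If exactly
one mask is empty, the image diagonal is returned as a defined, flagged
penalty so batch evaluation remains total; arithmetic means (with SD) over
a test set are reported by `glance()` and the CSV footer.

## Synthetic phantoms

`make_dataset()` emulates the *structure* of breast/thyroid ultrasound
datasets: 224×224 grayscale frames of multiplicative speckle (unit-mean
gamma noise — the standard first-order ultrasound speckle model — at
relative SD 0.3, smoothed with a 1 px Gaussian to give it spatial grain,
over a base intensity of 0.4), one elliptical lesion per frame with
semi-axes uniform in 8–40 px, contrast of random sign with magnitude
uniform in 0.1–0.3, and a 2 px feathered edge; the ground-truth mask is
the exact hard ellipse indicator. Unlabeled pool images are lesion-free
fields from the same model. Everything derives from one master seed.

What passing tests on phantoms do show: the operators' algebra, label
invariance, determinism, counting, and metric correctness are independent
of image content. What they do not show: anything about segmentation
accuracy on clinical images — phantoms have no shadowing, reverberation,
anisotropic speckle, multi-lesion cases or annotation noise, and a single
ellipse is far simpler than real lesion morphology. The phantom module is
infrastructure for verifying the toolkit, not a simulator of diagnostic
image quality.

## Numerical choices and degenerate inputs

* Per-file min–max normalization on load; zero-dynamic-range images map to
  all-zero. Masks binarize at half their dynamic range, robust to
  anti-aliased mask PNGs.
* RGB inputs collapse to BT.601 luminance before normalization (public
  breast-ultrasound PNGs are RGB-encoded grayscale).
* Written PNGs quantize to `round(255 p)/255` before encoding, so a
  load→write→load round trip moves no pixel by more than 1/255 and mask
  I/O is idempotent.
* Image resizing is bilinear (center-aligned, clamped); masks resize
  nearest-neighbor and re-binarize.
* `pixmix2` with a constant sum returns all-zero by the normalization
  rule; `hd95` of two empty masks is 0.
* All seeds are 32-bit; seeded draws are scoped with `withr::with_seed`,
  leaving the caller's RNG untouched.

## Problem sizes in the shipped checks

The test-suite and acceptance-script simulations use deliberately compact
instances — 64×64 or 48×48 phantoms, 16×16 random fields for the equation
oracles, a dummy 414-case table for the counting protocol, and a
20-labeled/100-unlabeled corpus for the end-to-end determinism check —
sizes at which the brute-force oracles (per-pixel loops, all-pairs
boundary distances, exhaustive 4×4 mask enumeration) are exact and cheap.
The operators themselves are resolution-independent, and the pipeline
defaults remain 224×224.

## Limitations

The package generates and evaluates datasets; it does not train
segmentation networks, so claims about which strategy best improves a
given architecture are outside its scope. One strategy per expansion plan
is enforced, mirroring the per-strategy experimental design (strategy
combination is an open research direction). Multi-lesion instance masks,
DICOM/NIfTI inputs, and physically realistic ultrasound simulation are
out of scope.
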