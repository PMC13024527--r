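---
title: "Dual-branch convolutional–capsule lesion detection: models and methods"
author: "duodet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch convolutional-capsule lesion detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duodet)
```

## The problem

Magnetically controlled capsule endoscopy (MCCE) produces thousands of
gastric frames per patient; screening them for early gastric cancer is
limited by reader fatigue and by the stomach's anatomical variability:
lesion appearance changes with viewing angle, patient posture, peristalsis
and illumination. Plain convolutional classifiers capture local texture well
but encode little about object pose and part–whole structure, which is
exactly the information that varies between frames of the same lesion.

`duodet` implements a dual-branch network that addresses this directly:

* a **convolutional branch** with ResNet50 topology (7×7 stride-2 stem,
  3×3 stride-2 max pool, four bottleneck stages, total stride 32) extracts
  local texture/edge features `Fc`;
* a **capsule branch** forms vector-valued *primary capsules* from `Fc`,
  lets them vote for *category capsules* through learned affine transforms,
  and aggregates the votes by iterative **routing-by-agreement**, producing
  a pose-aware map `Fv`;
* a **channel-attention gate** fuses the two streams,
  `F = α ⊙ Fc + (1−α) ⊙ φ(Fv)` with
  `α = σ(MLP(GAP([Fc;Fv])))`, where `φ` is a bias-free 1×1 channel-alignment
  convolution;
* two heads produce a softmax class probability vector (normal /
  erosion-like / polyp-like) and a sigmoid-bounded normalized bounding box
  `(cx, cy, w, h)`.

Training minimizes the composite objective
`L = L_CE + λ · L_smoothL1`, cross-entropy (optionally
inverse-frequency-weighted) plus a Smooth-L1 (Huber) box loss evaluated only
on images that carry a lesion box. `λ` defaults to 1 and is exposed in the
`loss` configuration block.

## Capsule mechanics

A capsule is a vector whose norm encodes presence probability and whose
direction encodes pose. The squash nonlinearity
`v = (‖z‖² / (1+‖z‖²)) · z/(‖z‖+ε)` (ε = 1e-8 guarding the zero vector)
compresses norms into [0, 1) while preserving direction. Routing starts from
zero logits (uniform couplings `1/K`), computes each category capsule as the
squashed coupling-weighted vote sum, and reinforces logits by the scalar
agreement between each vote and the emerging output; couplings are the
softmax of the logits over the category axis, so they always sum to 1 per
input capsule. Three iterations are the default (`capsule$r`), the
established convention for this procedure; the count is configurable.

Unstated design points were fixed as follows and are all configurable:
primary capsule dimension `d = 8`, category capsule dimension `d′ = 16`,
primary capsules per spatial cell chosen so that the capsule-forming 1×1
convolution emits 256 channels in the full profile (32 capsules/cell);
vote transforms are shared across spatial positions within a capsule type
(full per-pair transforms are memory-prohibitive and are retained only in
the functional API used by the oracle tests); and re-spatialization of the
`K` category capsules back to the grid is a spatial broadcast of the
concatenated `K·d′` vector, the simplest operator that restores the
convolutional branch's spatial dims.

**Gradient treatment of routing.** The backward pass treats the final
coupling coefficients as constants rather than unrolling the routing loop:
gradients flow through the weighted vote sums, both squash nonlinearities,
the vote transforms and the capsule-forming convolution. This is a
widely used simplification that keeps memory linear in the number of
capsules; the forward recursion is exact and is verified against a naive
triple-loop oracle in the test suite. All other layers backpropagate
exactly, and every layer's gradient is checked against central finite
differences.

## Fusion and ablation variants

The printed gate formula is purely channel-wise, and that is what is
implemented; no spatial gate is invented. The gate MLP is a
squeeze-excitation-style bottleneck (`Cc+Cv → Cc/16 → Cc`, ReLU between,
reduction configurable). A fixed-coefficient scalar fusion
(`α·Fc + (1−α)·Fv`) is retained as a diagnostic mode, and summation /
concatenation fusion exist as ablation variants. Seven variants are
constructible:

| id | change |
|----|--------|
| A0 | full model |
| A1 | remove the capsule branch (heads on `Fc`) |
| A2 | remove the convolutional branch (capsule branch on a 2-layer stride-2 image stem) |
| A3 | attention fusion → summation |
| A4 | attention fusion → concatenation (1×1-reduced) |
| A5 | all head-facing and gate pooling → global max pooling |
| A6 | two-layer FC head → single linear layer |

A2's image stem and A5's scope ("all pooling" read as the pre-head global
pools and the gate pooling; the backbone's internal stem max pool is
already max) were open design points; the choices above are the smallest
faithful readings. The capsule branch consumes the stage-4 map by default
(it may also consume the raw image, as in A2).

## Training protocol

Adam (`β₁ = 0.9`, `β₂ = 0.999`, weight decay 1e-4 on convolution/linear
weights), batch size 32, initial learning rate 0.005 cosine-annealed per
epoch to 1e-5:
`lr(e) = lr_final + ½(lr_init − lr_final)(1 + cos(πe/E))`, which passes
≈0.0025 at mid-schedule. Early stopping monitors validation accuracy (the
primary metric; switchable to loss) with patience 10. Data are split 8:2
into train/test with 10% of the training images held out for validation;
when a grouping column (e.g. patient id) is present, whole groups stay on
one side of the split. "Momentum coefficient 0.9" is read as Adam's β₁.
Secondary fine-tuning is the same loop warm-started from a checkpoint.

Class weighting defaults to inverse-frequency weights computed from the
training labels (minority lesion classes are upweighted); regression
supervision on lesion-free images is masked out, the standard detection
convention.

## Profiles and problem sizes

Three geometry profiles bundle the resolution/width choices:

* **full** — 224×224 input, width multiplier 1, 2048-channel stage-4 map,
  ~28M-parameter scale. Used for geometry contracts; CPU training at this
  scale is not attempted.
* **desk** — 64×64 input, width multiplier 0.25 (512-channel map,
  ≈1.6M parameters). This is the profile used for end-to-end learnability:
  2,000 synthetic frames, 8 training epochs. It reaches ≥90% held-out
  accuracy in a few minutes on one CPU.
* **micro** — 48×48, width 0.25 with fewer capsules per cell. Used for
  multi-seed trend reports (the A0-vs-A1 capsule-contribution trend over
  three seeds, 400 frames, 5 epochs) and quick reproducibility checks,
  where several full trainings must stay cheap.

The channel contracts are per-profile: the 2048-channel output applies to
the full profile; reduced profiles document their own `out_channels`.
Numbers obtained at different profiles are never compared silently.

## Synthetic data: what it emulates and what it does not

No public MCCE screening dataset with this label structure exists, so the
package ships a seeded generator. It emulates: the screening class mix
(56% normal; lesions split 3:1 erosion-like vs polyp-like), smooth reddish
mucosa texture (low-frequency noise, vignette, illumination jitter ±10%),
two lesion archetypes (irregular darker patch with texture discontinuity;
bright shaded ellipse with a specular highlight), pose variability
(rotation ±25°, translation ±12%, scale 0.8–1.25×) applied coherently to
lesion and box, and ground-truth normalized boxes. Generation is
byte-identical given the spec (Mersenne-Twister pinned).

It does **not** emulate real mucosal microtexture, specular fluid
artifacts, peristaltic deformation, anatomical site context, or realistic
lesion morphology. Passing tests therefore demonstrate that the
architecture, losses, optimization and evaluation machinery behave as
specified and that the model can learn pose-varied, intensity-defined
lesion classes — not clinical-grade performance on real endoscopy.

The robustness protocol perturbs brightness and contrast by ±20%
(multiplicative, clipped; the underlying study describes the perturbations
only as "mild", so ±20% is a documented choice) and applies random flips
plus small rotations with boxes updated and clipped coherently.

## Numerical choices

* Squash guard ε = 1e-8; probability clamp in the cross-entropy at 1e-12
  (clamping warns rather than failing).
* Huber knee at |x| = 1 with the linear branch `|x| − 0.5`; symmetry is
  required of a residual loss even where source material prints the outer
  branch without the absolute value.
* Youden-optimal thresholds scan the observed scores; ties break toward the
  lowest threshold (favoring sensitivity). AUC ties count ½ (average-rank
  Mann–Whitney), and the rank and trapezoid routes agree to 1e-10.
* Zero-denominator diagnostic metrics are reported as `NA`, never as 0.
* Sample sizes round half-up (matching all four worked planning numbers:
  78.0→78, 97.5→98, 73.0→73, 91.25→91), with a ceiling option for the
  conservative convention. Exact normal quantiles and the conventional
  2–3-digit constants (1.96, 0.842) give identical rounded results on the
  worked inputs.
* Max-pool backward routes gradient to the first-encountered argmax;
  batch-norm uses running statistics (momentum 0.1) in inference mode.

## Known limitations

* Routing gradients use the fixed-coupling approximation described above.
* The convolutional backbone is randomly initialized; there is no
  pretrained-weight path, so absolute accuracies on real data would require
  substantially more data/epochs than the desk-scale demonstrations.
* Uncertainty calibration is out of scope (named but never specified in the
  source material's loss section); no calibration curves are produced.
* The spatial half of a "channel–spatial" gate has no printed formula and
  is deliberately not invented; the gate is channel-wise.
* Single box per image; no anchors, no IoU-family losses.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
every reported quantity from scratch: the four sample-size planning
numbers, the worked-example diagnostic metrics (sensitivity/specificity/
precision/Youden/F1 from the published 3-class screening confusion matrix),
the cosine schedule waypoints, the routing-oracle agreement error, a full
desk-profile training run (2,000 frames) with test accuracy, lesion-vs-
normal AUC, sensitivity/specificity, perturbation deltas in percentage
points, and the micro-scale A0-vs-A1 accuracy gap over three seeds.
```
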