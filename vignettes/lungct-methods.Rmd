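---
title: "Methods: lung-field segmentation and hybrid CNN-BiGRU classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung-field segmentation and hybrid CNN-BiGRU classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`lungct` implements a slice-level, three-class (Benign / Malignant / Normal)
classification pipeline for 2-D axial chest-CT images. The design principle
is to constrain the input anatomically before classification: isolate the two
air-filled lung fields, bias the retained pixels toward plausible lesions,
and only then hand the image to a high-capacity classifier. The pipeline is

1. load as 8-bit grayscale, resize to 512×512;
2. lung-field segmentation (CLAHE → fixed threshold → morphological
   refinement → edge-guided hole filling → component selection → mask
   superposition);
3. nodule-candidate masking (keep pixels with intensity strictly below 140);
4. resize to 224×224, replicate to three channels;
5. classify with a convolutional backbone feeding a stacked bidirectional-GRU
   gating head and a 3-way softmax.

Because clinical CT datasets of this kind are rarely redistributable, the
package ships a seeded phantom generator with per-image ground-truth masks.
All quantitative claims made by the test suite and by
`scripts/acceptance.R` are measured on these phantoms, not on patient data.

## The phantom generator

`generate_phantom()` renders an axial-slice caricature: a dark background
(mean 10), a bright body ellipse (mean 180), two dark lung ellipses
(mean 40) placed symmetrically about the vertical midline with seeded
geometric jitter (±2% centre, ±4–5% axes), and a class-dependent nodule of
mean intensity 120 inside one lung. Benign nodules are small circles
(radius 6–12 px at 512×512) with smooth margins; malignant nodules are
larger (14–28 px) with an irregular margin produced by low-frequency
sinusoidal perturbation of the radius (harmonics 2–5, relative amplitude
0.35). Gaussian intensity noise (sd 8) is added and clipped to `[0, 255]`.

The intensity ordering background < lung < nodule < body is enforced by the
spec constructor because two downstream thresholds rely on it: the
binarisation threshold must separate lungs from the body wall, and the
below-140 candidate rule must retain nodule pixels while the body wall is
excluded by the lung mask.

What the phantom does **not** emulate: vessels, airways, ribs and the
mediastinum, HU calibration, scanner noise spectra, and partial-volume
effects. Passing the phantom oracles therefore demonstrates that the
implementation is internally correct and that the pipeline's stages compose
as intended — it does not demonstrate clinical performance on real CT.

## Segmentation

`segment_lungs()` composes six deterministic steps; every parameter lives in
`segmentation_params()`.

* **CLAHE** (`EBImage::clahe`), clip limit 2.0, 8×8 tiles. Inputs whose
  sides are not tile multiples are edge-padded and cropped back.
* **Binarisation** at a fixed threshold (default 128) with dark-foreground
  polarity: air-filled lungs are low-intensity, so a pixel is foreground iff
  it is *strictly below* the threshold.
* **Morphological refinement**: closing (disk radius 3) to bridge small
  gaps, erosion (radius 2) to detach spurious attachments, then a second
  closing with a *larger* disk (radius 7) to re-seal erosion damage. The
  constructor enforces the radius ordering.
* **Edge-guided hole filling**: interior holes — background regions not
  connected to the image border — are filled, with Canny edges of the
  enhanced image (Gaussian sd 1.2, Sobel gradients, non-maximum
  suppression, hysteresis 50/150 on gradient magnitude) sealing boundary
  leaks: a cavity whose rim is breached in the mask but traced closed by
  an edge still counts as interior. Edge pixels guide hole detection but
  never enter the output mask themselves — thin edge chains must not
  bridge separate components, which would corrupt component selection.
  Filling iterates to a fixpoint (a filled cavity's edge ring becomes a
  new interior hole) and is capped at `max_hole_fraction` (default 5%) of
  the image area: under dark-foreground polarity the body wall is itself
  an enclosed zero-region of the mask, and uncapped filling would flood
  the entire frame. The cap cleanly separates nodule-scale cavities
  (< 1% of the frame) from the body ring (tens of percent).
* **Component selection**: keep up to the two largest connected components
  (two lung fields per axial slice) with area ≥ 500 px, discarding
  components that touch the border (the surrounding dark background).
* **Superposition**: the final mask gates the *raw* resized image by
  default (`use_enhanced_for_output` switches to the CLAHE output).

On 20 default phantoms the final mask reaches a mean intersection-over-union
above 0.95 against the ground-truth lung masks; the acceptance suite asserts
the design bound of 0.80.

## Nodule-candidate masking

`candidate_mask()` marks pixels strictly below 140 as potential nodule
regions. Two guards make this meaningful after segmentation: pixels equal
to 0 (the suppressed background, trivially below any threshold) are
excluded, and the rule is restricted to the lung mask. Both guards are
flags, so the unrestricted literal reading is also available. This stage
biases the classifier's input toward candidate regions; it is not clinical
nodule detection.

## Augmentation

Training-stream transforms follow fixed mild ranges: rotation U(0°, 30°),
signed translation up to 0.25 of each side, x-shear U(0, 0.5) rad, zoom
U(0.975, 1.025), independent fair-coin horizontal/vertical flips. The warp
applies rotate → shear → zoom → shift → flips about the image centre by
inverse mapping; out-of-frame source coordinates are clamped to the nearest
edge pixel (nearest-edge replication fill), and image content is
interpolated bilinearly. Augmentation is applied only to the training
stream; monitor/test images are never transformed. The transform order and
the flip probability (0.5 each) are package conventions; the shear is
applied along x only.

## Split and label encoding

`split_manifest()` holds out exactly `test_per_class` images per class
(default 150), sampled without replacement under a seed; the training set is
the exact complement. On a 530/536/534 manifest this yields the balanced
450-image test set and a 1,150-image training set (380/386/384). The same
held-out set serves both early-stopping monitoring and final evaluation —
the two roles are deliberately conflated; users who want a leakage-free
protocol can carve a separate monitor set from the training split
themselves. Labels are one-hot encoded in the fixed alphabetical order
Benign, Malignant, Normal.

## The hybrid classifier

The head follows a fixed width contract: a 1024-dimensional projected
feature vector, reshaped to a one-step sequence, through two stacked
bidirectional GRU layers (256 then 128 units per direction, concatenated:
widths 512 and 256), two ReLU dense layers (256, 128) with dropout (0.5,
0.3), and a 3-way softmax. With a one-step sequence and a zero initial
state, the GRU recurrence carries no temporal information: the output is
`h = z ⊙ tanh(W_c x + b_c)` with update gate `z = σ(W_z x + b_z)`, i.e. a
learned input-conditional feature-weighting. Consequently the recurrent
kernels cannot influence the output and are not allocated, and the reset
gate (allocated for parameterisation fidelity) receives an exactly zero
gradient — a property the test suite asserts by finite differences.

### Backbone

The shipped backbone, `tiny_cnn`, is a from-scratch CPU network: an
optional 2× average-pool stem, three blocks of (3×3 convolution →
affine-free instance normalisation → ReLU → 2×2 max-pool) with channel
widths 8/16/32, and global average pooling, followed by a linear projection
to the 1024-wide feature interface. Convolutions are evaluated as im2col
patch-matrix products so the arithmetic runs through BLAS; gradients are
analytic and verified against finite differences.

Two design notes:

* **Instance normalisation** (per-sample, per-channel standardisation over
  the spatial extent) is what makes a three-block network trainable from
  scratch in tens of epochs on about a hundred images: it conditions the
  optimisation the way batch normalisation does while remaining
  deterministic and batch-free, which keeps repeated runs bit-identical.
  Without it the masked inputs — mostly zeros, with the discriminative
  lesion occupying well under 1% of the frame — leave the class signal
  orders of magnitude below the common-mode activation scale and the
  network sits at chance for longer than the epoch budget.
* **`densenet201` is recognised but rejected at build time.** Its value is
  the ImageNet pretraining; pretrained weights are not bundled, and a
  randomly initialised 201-layer network would be slower and *worse* than
  the tiny backbone. The projection to 1024 keeps the head contract
  identical for any backbone, so the architecture checks do not depend on
  the backbone choice.

### Training protocol

Adam with categorical cross-entropy. The `train_config()` defaults record a
fine-tuning protocol (learning rate 1e-5, backbone frozen except the final
convolution block, batch 32, ≤30 epochs, early stopping on the monitored
loss with patience 5, best-epoch weights restored). Training the tiny
backbone from scratch uses `freeze_policy = "none"`, learning rate 1e-3 —
1e-5 is far too small to move a randomly initialised network within 30
epochs — and an early-stopping patience of 10 rather than 5: a from-scratch
run spends its first ~10 epochs near chance level, where the monitored loss
wanders and a patience of 5 can abort training before learning begins. The
fine-tuning defaults keep patience 5. A reduce-on-plateau learning-rate schedule is available
(`lr_plateau_factor`) but disabled by default: on short from-scratch runs
the monitored loss is noisy near chance level and premature decay freezes
the model.

All shuffling, augmentation draws and dropout masks are seeded from the
training seed, and the engine is single-threaded double precision, so
identical calls produce bit-identical histories, weights and reports.

## Evaluation

`confusion()` fixes rows as true classes and columns as predicted classes.
`compute_metrics()` derives one-vs-rest `Tp/Fp/Fn/Tn` per class, precision
`Tp/(Tp+Fp)`, recall `Tp/(Tp+Fn)`, their harmonic-mean F1, and overall
accuracy as trace over total; divisions by zero yield a flagged sentinel
rather than `NaN`. Class-wise accuracy (`cm[i,i]/rowsum(i)`) is numerically
identical to per-class recall and is reported to two decimals, while
precision/recall/F1/accuracy render at one decimal. A brute-force
per-sample tally serves as the test oracle for all of these.

## Ablation harness

`run_ablation()` performs three cumulative runs on identical data, split and
seeds: segmentation with a dense head, plus nodule masking, plus the BiGRU
head. The dense baseline replaces the two BiGRU layers with plain ReLU
layers of matched widths (512, 256) so parameter counts stay comparable.
Augmentation settings are held constant across rows. A stage-0 raw-image
row is available but off by default. Preprocessing variants are computed
once and shared, so rows differ only in the toggled stage.

## Problem sizes and runtime

The phantom study design used throughout the tests and the acceptance
script: 20 phantoms for the segmentation and candidate-mask oracles; 60
phantoms per class (15 per class held out) for end-to-end training, batch
16, at most 30 epochs, three independent seeds. On a single CPU core one
training run takes a few minutes; the full acceptance script completes in
roughly ten.

## Known limitations

* The phantom is a geometric caricature; no claim about real-CT accuracy
  follows from phantom results.
* The fixed binarisation threshold assumes roughly standardised 8-bit
  intensity; heavily windowed or inverted inputs need re-configured
  thresholds.
* If the body wall is locally thinner than the diameter of the second
  closing disk (15 px at defaults), closing can bridge the lung fields to
  the surrounding background; border exclusion then discards everything
  and the pipeline emits its empty-mask warning with an all-zero output.
  Roughly one phantom in sixty draws such a geometry; on real CT, reduce
  `close2_radius` if the chest wall can be very thin at the imaging
  resolution.
* The hole-filling cap (`max_hole_fraction`) trades completeness for
  safety: a genuine interior cavity larger than the cap would not be
  filled.
* Sequence length is fixed at one step by design; the recurrent layers are
  gating units, not temporal models, and no multi-step mode exists.
* Pretrained backbones are out of scope offline; transfer-learning
  configurations are expressed but not exercisable without weights.
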