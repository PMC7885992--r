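---
title: "Methods: two-step calcium analysis in polar-domain IVOCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step calcium analysis in polar-domain IVOCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `octcalc`, and what the phantom-based validation does
and does not establish about real intravascular OCT data.

## The processing model

A pullback is a stack of polar frames; each frame is a matrix with
A-lines (θ) as rows and radial samples (r) as columns. The pipeline
never leaves this domain. Stages, in order:

1. **Guidewire shadow detection.** Per-A-line tissue energy is summed
   beyond the catheter radius (default 8 px). Over all circular windows
   of admissible width the detector minimises the summed below-threshold
   margin `Σ (energy − t)` with `t = 0.35 × median(energy)`; if no
   window goes below zero the frame has no shadow. Minimising the margin
   rather than the raw sum makes the optimum cover exactly the
   sub-threshold block, so the window width does not need to be known in
   advance.
2. **Lumen detection.** The published system delegates lumen
   segmentation to a separate deep network; `octcalc` instead uses a
   transparent substitute adequate for phantom work: a bright-onset edge
   score per pixel, maximised along each A-line subject to a circular
   continuity constraint (|Δindex| ≤ 3 px between neighbouring A-lines)
   solved by dynamic programming anchored at the most confident A-line.
   Guidewire A-lines are filled by circular interpolation. Users with a
   dedicated lumen segmenter can bypass this via `lumen_override`.
3. **Alignment and ROI.** Every A-line is shifted left so the lumen
   boundary lands in column 1, and 200 columns (1 mm at 5 μm/px) are
   kept. The shift offsets are retained (`preproc_context`), making the
   transform exactly invertible for every retained pixel
   (`restore_geometry`).
4. **Despeckling.** A normalised, separable 7 × 7 Gaussian with σ = 1
   and reflective boundaries.
5. **Step 1 — frame detection.** A 3D CNN over 5-frame windows. The θ
   padding of the input window is parametric: each depth slice receives
   the last A-line of its preceding frame as top padding and the first
   A-line of its following frame as bottom padding (a pullback is a
   helix, so the frame above/below in θ is the neighbouring frame); the
   first and last frames supply their own boundary A-lines. At the
   acquisition scale the architecture is five blocks of 3D convolution
   (kernel 3 × 5 × 5, stride 1) + batch normalisation + ReLU, each
   followed by 2 × 2 max pooling over (θ, r) with depth never pooled,
   then FC-1024 with ReLU and dropout and a 2-class softmax. The
   published filter list names four counts (96, 128, 256, 324) for five
   convolution layers; the fifth repeats 324 here and the whole list is
   configurable. Argmax ties label a frame "other" — the conservative
   direction, which avoids spurious lesions.
6. **Label cleanup.** Morphological opening then closing of the binary
   frame-label sequence with a flat, centred structuring element of 5
   frames. The sequence is zero beyond its ends: a positive run shorter
   than 5 touching the pullback boundary is removed, and boundary gaps
   are never filled. Closing is computed on an explicitly zero-extended
   domain because its erosion needs the dilated values beyond the array
   ends; an exhaustive equivalence test against a run-length oracle over
   all 2^14 length-14 sequences pins this behaviour down.
7. **Step 2 — segmentation.** A SegNet-style encoder–decoder: VGG-16
   convolution arrangement (13 encoder convolutions in five stages),
   2 × 2 stride-2 max pooling that records argmax indices, a mirrored
   decoder that unpools through those indices, and a 1 × 1 convolution
   with per-pixel softmax. Inside convolution layers θ is padded
   circularly — the vessel wall is a cylinder, and for deep feature maps
   the circular wrap is the natural continuation of the parametric
   input-padding idea, which is only defined for image-domain rows; r is
   zero-padded. Only frames inside cleaned lesion intervals are
   segmented (the two-step protocol); a switch (`allow_empty`,
   `one_step`) exposes the one-step alternative for comparison studies.
8. **CRF refinement.** A fully connected CRF with unary `−log p` and a
   single position-only Gaussian smoothness kernel; the kernel "sizes"
   1.2 (r) and 1.1 (θ) are interpreted as standard deviations in pixels,
   the published text not stating units. No appearance/bilateral kernel
   is used because only smoothness parameters are ever optimised in the
   source system. Mean-field messages are computed exactly through the
   kernel's separable structure (`K_θ Q K_r`, self-pair excluded, θ
   wrapping circularly) rather than by truncated convolution, so the
   fast path agrees with the dense O(N²) oracle to machine precision;
   probabilities are renormalised after every one of the 10 passes.
9. **Missing-frame interpolation.** An empty mask strictly inside a
   lesion with nonempty masks on both sides is replaced by thresholding
   the linear interpolation of the neighbours' signed Euclidean distance
   transforms. Signed-distance morphing is chosen over probability or
   mask averaging because it yields a sharp binary shape that moves
   continuously between the neighbours; identical neighbours reproduce
   themselves exactly.
10. **Quantification.** Angles are measured catheter-centrically (number
    of mask-positive A-lines × 360/448°), which is exact in the polar
    domain the pipeline works in but can differ from lumen-centroid
    conventions on eccentric lumens. Depth is measured from the lumen
    boundary (column 1 after alignment) to the leading calcification
    edge. Mean thickness averages per-A-line radial extents over all
    positive A-lines of a lesion; the calcium score uses the *maximum*
    per-A-line thickness, and all three score thresholds are strict
    inequalities. Frame pitch 0.2 mm (36 mm/s ÷ 180 fps) and radial
    pitch 5 μm (200 px ≙ 1 mm) are defaults, overridable per pullback.

## Training protocol

Both networks train with Adam (initial learning rate 0.001), a stepped
schedule multiplying the rate by 0.2 every 5 epochs, at most 50 epochs,
and early stopping after 5 consecutive epochs without validation-loss
improvement (best weights kept). Class imbalance in WCE training is
handled by inverse-median-frequency weights, `w_c = median(f)/f_c`, with
`f_c` the pixel frequency of class *c* over the frames in which it
appears. The Tversky α/β are not published; 0.7/0.3 is the package
default — the standard recall-weighted choice, consistent with the
sensitivity gains the loss is selected for — and both are configurable.
Dice/Tversky losses use soft probabilistic counts during training and
hard counts at evaluation. Splits are always by pullback
(`crossval_split`), never by frame.

Two adaptations matter at desk scale. First, the drop period of the
learning-rate schedule is expressed in epochs; with a few hundred
training windows a single pass contains only a handful of optimiser
steps, so `train_config(epoch_repeats = )` lets one schedule epoch span
several passes, keeping the number of steps per learning-rate stage
comparable to a large-data setting without touching the schedule
itself. Second, both trainers augment by random circular θ rolls
(padding rows rebuilt afterwards): the vessel is rotationally
symmetric, a lesion is equally plausible at any angle, and the
flattened-feature FC head would otherwise memorise angular position on
small phantom sets.

## The phantom generator

`phantom_spec()`/`generate_pullback()` render, per frame: a lumen
boundary `base + A·sin(θ) + A'·sin(2θ)` with a slow random radial drift
across frames; a 2 px bright boundary band (0.85) and tissue decaying
exponentially with depth (0.6·e^{−a·d}); calcified regions attenuated to
0.3 × the local background with a one-pixel bright leading edge when at
least 3 px thick ("signal-poor with sharply delineated borders"); a dark
wedge-shaped guidewire shadow; and multiplicative gamma speckle of
configurable standard deviation (mean 1). All randomness flows from one
integer seed, output is quantised to the 16-bit TIFF grid so fixtures
round-trip losslessly, and the ground truth (masks, per-frame labels,
lumen indices) is returned with the images.

The generator reproduces the image *properties the pipeline depends on*,
not OCT physics: no coherent speckle statistics, no catheter optics, no
real tissue heterogeneity (lipid pools, fibrous caps, side branches), no
motion artefacts. Passing the phantom studies therefore demonstrates
that the implementation is correct and that the two-step design behaves
as intended under controlled conditions; it does not certify clinical
performance, which requires training on expert-labelled pullbacks.

## Study sizes and stochastic checks

The validation studies use pullbacks of 60 frames × 64 A-lines × 64
radial px (ROI depth 48 px), with 2–3 lesions per pullback (5–9 frames,
half-widths 6–16 A-lines, depths 1–8 px, thicknesses 5–16 px; lesion
prevalence roughly 15–35 % of frames), four training pullbacks (the
fourth serving as validation) and two held-out test pullbacks — sizes at
which the complete train-and-evaluate cycle runs in minutes on one CPU.
The tiny networks use three detector blocks (4/8/8 filters, 3×3×3
kernels, FC-16) and a two-stage segmenter (8/16 filters). Trained-model
metrics are stochastic: at the default study seed the held-out frame F1
is ≈ 0.92 and the two-step pixel Dice ≈ 0.78, but individual seeds can
land a few hundredths lower on either metric; the fixed-seed study in
the test suite and the seeded acceptance script make any given run
reproducible bit for bit.

The repeat-pullback reproducibility study renders the same lesion
geometry under two independent speckle realisations and pushes both
through the automatic measurement chain (guidewire and lumen detection,
alignment, quantification). Because lesions are defined relative to the
lumen, attribute differences isolate the measurement chain's sensitivity
to speckle; scores are expected to be identical and attribute
differences within two pixel-equivalents.

## Numerical choices and degenerate inputs

- Probabilities are clamped at 1e-12 before logarithms; losses carry a
  1e-6 smoothing term arranged so that Tversky(α = β = 0.5) equals Dice
  to 1e-12.
- CRF kernel entries below 1e-12 are zeroed; the dense test oracle is
  guarded to ≤ 32 × 32 images.
- Max-pooling ties resolve to the first element in column-major order;
  odd feature-map extents drop the trailing row/column (floor pooling)
  and unpooling restores the stored pre-pool shape.
- Detector argmax ties go to "other"; `classification_metrics` reports a
  zero-denominator metric as `NA`, never 0.
- An all-dark frame is a lumen-detection error (not a silent zero); a
  frame with no shadow yields an empty guidewire interval, which is
  valid.
- Empty lesion intervals, empty masks and zero-lesion pullbacks flow
  through the pipeline producing empty-but-well-formed outputs.

## Known limitations

- The lumen detector is a gradient/DP substitute, not the published
  deep-network segmentation; on real data it should be replaced via
  `lumen_override`.
- The guidewire search cost and width range are package choices; the
  cited dynamic-programming method is not fully specified in the source
  text.
- Catheter-centric angles differ from lumen-centroid angles on eccentric
  lumens.
- Pretrained (e.g. VGG-16-derived) encoder initialisation is an optional
  hook: `train_segmenter(init_params = )` accepts externally built
  weight arrays by name. The default is seeded random initialisation so
  the package has no download dependency.
- The published receptive-field figure for the segmenter is not
  reproduced as a check because its derivation is not stated.
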