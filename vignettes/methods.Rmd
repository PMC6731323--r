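---
title: "Tumour segmentation and Ki67 hotspot detection in IHC slides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumour segmentation and Ki67 hotspot detection in IHC slides: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ki67 immunohistochemistry (IHC) stains proliferating nuclei brown (DAB
chromogen) against a haematoxylin-blue counterstain.  Scoring the Ki67
labelling index requires knowing *where the tumour is*: positivity in
benign epithelium, stromal cells or lymphocytic infiltrate must not enter
the score.  `ihcseg` implements a patch-based convolutional classifier
that annotates tumour versus non-tumour tissue on whole-slide images,
plus the downstream step pathology cares about: finding the
proliferation *hotspot*, the circle-sized region of highest
Ki67-positive density inside the predicted tumour mask.

Everything is testable end-to-end without clinical material through a
synthetic pseudo-slide generator that produces IHC-like images with
exact, paired ground truth.

# The classifier

The network is deliberately small — four learnable layers on 64 × 64
RGB patches at ~0.5 µm/px:

| stage  | operation                        | spatial size |
|--------|----------------------------------|--------------|
| input  | mean-normalised RGB              | 64 × 64 × 3  |
| conv1  | 32 kernels, 5 × 5, stride 1 + ReLU | 60 × 60 × 32 |
| conv2  | 64 kernels, 5 × 5, stride 1 + ReLU | 56 × 56 × 64 |
| pool   | 2 × 2 max, stride 2              | 28 × 28 × 64 |
| fc1    | 1024 units + ReLU                | —            |
| fc2    | 512 units + ReLU + dropout 0.5   | —            |
| output | K = 2 softmax                    | —            |

Feature-map sizes follow the standard valid-convolution convention
`(W + 2·pad − M)/stride + 1` (`feature_map_size()`).  A commonly printed
shorthand for this arithmetic omits the `+ 1`; we use the full
convention, under which the 2 × 2 stride-2 pool halves even inputs
(60 → 30, 56 → 28) exactly as expected.  Padding is zero everywhere
(valid convolutions); no source for the architecture states padding, and
valid convolution is the assumption that reproduces the published size
chain 64 → 60 → 56 → 28.

Choices the architecture description leaves open, fixed here once:

* **Loss.** Cross-entropy over the softmax output — the canonical
  pairing for a softmax classifier.
* **FC activations.** ReLU after each fully connected layer except the
  output.  (Only the convolutional ReLUs are ever stated explicitly.)
* **Mean normalisation.** Per-channel means of the training set are
  subtracted from `[0, 1]`-scaled RGB and stored with the model, so
  inference applies exactly the training-time normalisation.
* **Initialisation.** Fan-in-scaled ("He") normal weights, zero biases,
  seeded; the output layer uses a 1/fan-in variance scale.

Training is plain stochastic gradient descent with learning rate 0.001,
momentum 0.9, batch size 25, 15 epochs, and inverted dropout (rate 0.5)
after fc2, active only during training.  There is no learning-rate
schedule, early stopping or checkpoint selection.  The engine
(`src/cnn.cpp`) is a compact single-precision im2col + BLAS
implementation with explicit backward passes; training and inference are
deterministic given the seed.

The infiltrate classifier ("is this tile lymphocytic infiltrate?") is
*the same* `network_spec()` trained on infiltrate / non-infiltrate
labels — there is no separate code path, only different training data.

# Whole-slide pipeline

1. **Tissue detection.** A 64 × 64 tile is tissue iff its mean intensity
   over all pixels and channels (8-bit scale) is below 235; glass
   background sits near 249.
2. **Tiling.** Overlapping tiles on a 32-px stride lattice (50%
   overlap).  How overlapping predictions combine is unstated in the
   method's description; we average per lattice cell, which is the
   least-committal choice and makes the map refine smoothly as the
   stride shrinks.  Cells no tile covers are *background* (`NA`), never
   "probability 0".
3. **Infiltrate exclusion.** Cells whose infiltrate probability is
   ≥ 0.5 are forced to non-tumour and flagged; the operation is
   idempotent.
4. **Pseudo-colour.** Red p > 0.75, orange 0.65 < p ≤ 0.75, yellow
   0.55 < p ≤ 0.65, blue otherwise.  Bins are half-open with the upper
   edge in the lower bin, matching the strict inequality "p > 0.75" of
   the red bin.
5. **Binarisation.** Tumour mask = cells with p > 0.55 (the lower edge
   of the lowest tumour colour).  The exact cut-off used for published
   validation tables is not stated; 0.55 is the value consistent with
   the colour key and is exposed as configuration.

# Hotspot identification

Within the (predicted or known) tumour mask:

1. **DAB extraction.** Ruifrok–Johnston H-DAB colour deconvolution;
   pixels with DAB optical density > 0.15 are candidate-positive,
   cleaned by a radius-1 morphological opening and a 20-px minimum
   component area, then intersected with the tumour mask.  The source
   method names only "threshold and morphological operations"; these are
   the minimal standard operators, all exposed as parameters.
2. **Centroids.** One per 8-connected component of the DAB mask.
3. **Subtractive clustering** (Chiu): potentials
   `P_i = Σ_j exp(−4‖x_i−x_j‖²/ra²)`, iterative centre selection with
   influence subtraction at radius `rb`, acceptance/rejection at
   0.5/0.15 of the first potential and the distance criterion in
   between.  Defaults `ra = 200 px`, `rb = 1.5·ra` are Chiu's
   conventions; no published values exist for this pipeline.
4. **Circle scoring.** A 100-px-diameter circle (~50 µm at 0.5 µm/px)
   at every cluster centre; the Ki67 ratio is DAB-positive pixels over
   total circle pixels (border-clipped circles use the clipped area).
   A circle is a hotspot when the ratio exceeds 0.20.  The ratio uses
   the whole circle area, not the tissue area within it, following the
   "DAB area to the total area" description.
5. **Banding.** Low/medium/high proliferation bands are configurable
   cut-offs (`band_proliferation()`); no canonical numeric bands are
   fixed by the method, so none are hard-coded.

# Validation metrics

Pixel confusion counts (positive = tumour) at the annotation downsample
(default 8×, approximating annotation at an apparent 10× magnification),
evaluated **over tissue pixels only** by default — including glass would
inflate true negatives arbitrarily; the flag is exposed because the
evaluation universe is a genuine open question.  From the counts:
TPR, TNR, FPR, FNR, PPV, NPV and Dice = 2TP/(2TP+FP+FN).  Cohort
summaries are unweighted per-slide mean ± sd.  Metrics with zero
denominators are reported as `NA` ("undefined"), with a warning, and
excluded from cohort means — never silently coerced to 0.

# The synthetic pseudo-slide generator

`generate_pseudo_slide()` renders: glass at grey level ~249 with σ = 2
Gaussian noise (all channels ≥ 240, so the MI < 235 rule is exercised
realistically); pale tissue fields; and nuclei as anti-aliased filled
ellipses with jittered radius, eccentricity, orientation and hue.
Region classes are tumour (dense, round, radius 4–6 px), benign
epithelium (sparser), stroma (sparse, elongated) and lymphocytic
infiltrate (very dense, small, darker blue).  Ki67-positive nuclei are
DAB-brown `(0.55, 0.33, 0.14)`; negatives are haematoxylin-blue
`(0.26, 0.28, 0.58)`.  Within each tumour region exactly
`round(n · f)` of its `n` nuclei are positive, so the realised fraction
matches the requested one to 1/n; benign epithelium gets a sparse 2%
positivity, as real non-tumour epithelium is not uniformly negative.

Ground truth is exact by construction: the label mask *is* the
rasterised annotation set (at a default 8× downsample), and the
DAB-positive mask records exactly the rendered positive-nucleus pixels.
`plant_hotspot()` raises the positive fraction inside a disc to a
target by recolouring the minimum number of existing nuclei,
keeping image and masks consistent.

What the generator does **not** emulate: chromatin texture, stain
variation between labs, tissue folds, out-of-focus regions, nuclear
pleomorphism, and the fragmented architecture of low-tumour-content
biopsies.  Passing tests on synthetic slides therefore demonstrate that
the pipeline's machinery is correct and that the classifier can learn
colour/density/texture class differences — not that it reaches any
particular accuracy on clinical slides, where published performance is
substantially lower than on these fixtures.

# Numerical and design notes

* **Rasterisation contract.** Pixel-centre coverage in half-open image
  coordinates: mask pixel (u, v) at downsample d is labelled by the
  polygon containing ((u+0.5)d, (v+0.5)d) under the even-odd rule.
  This is brute-force-checkable and is tested against an independent
  point-in-polygon oracle.  Overlaps resolve by label priority
  infiltrate > tumour > non-tumour (the source material is silent on
  overlapping annotations); equal priority resolves by region order.
* **Patch purity.** A training patch must have ≥ 90% of its pixels in
  one class ("within the annotated region" is the only guidance);
  purity is monotone: stricter thresholds select a subset.
* **Softmax.** Stabilised by max-subtraction; invariant under additive
  shifts by construction.
* **Augmentation.** Dihedral transforms only (flips and right-angle
  rotations).  Photometric jitter is deliberately excluded: the
  classifier must stay sensitive to stain colour.
* **8-connectivity.** DAB components are labelled 8-connected (a
  dedicated C++ labeller; the EBImage labeller is 4-connected).
* **Degenerate inputs.** Zero-radius hotspot discs are rejected;
  a single clustering point is its own centre; empty masks yield empty
  centroid lists; empty tumour masks yield empty DAB masks with a
  warning.

# Problem sizes used by the tests and acceptance script

Chosen once as the package's standard demonstration scale: training
uses 1,000 balanced 64 × 64 patches (500 per class) extracted at
stride 32 from a 2048 × 2048 pseudo-slide, trained with the exact
standard configuration (15 epochs, batch 25); held-out evaluation uses
500 patches from a geometrically different slide.  The label-shuffled
control uses 600 patches for 5 epochs — chance-level held-out accuracy
is insensitive to both numbers.  The infiltrate classifier trains on a
balanced 150-per-class set (the scarce infiltrate class topped up by
dihedral augmentation) for 8 epochs; an under-trained infiltrate model
is the main failure mode of the exclusion stage, so it gets the extra
epochs even though the tumour/non-tumour task does not need them.
End-to-end segmentation runs on a
2048 × 2048 slide at stride 32; hotspot recovery on a 1280 × 1280
slide with a planted disc (radius 150 px, fraction 0.5 over an ambient
0.05).  On these fixtures the pipeline typically reaches held-out patch
accuracy ≥ 0.95 and Dice ≥ 0.85 — synthetic scenes are deliberately
easier than clinical slides, and the tests assert exactly those bounds;
the acceptance script recomputes them from scratch at run time.

# Known limitations

* The CNN engine is CPU-only, single-threaded BLAS; training at the
  demonstration scale takes minutes, not seconds.
* Only plain PNG/TIFF pseudo-slides are read; pyramidal vendor WSI
  formats are out of scope (the reader interface is pluggable).
* Proliferation banding ships without canonical cut-offs.
* Hotspot scoring measures area ratio, not per-cell counts; nucleus
  instance segmentation is explicitly out of scope.
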