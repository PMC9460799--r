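---
title: "Methods: drowsiness recognition, attention attribution, and feature-geometry diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drowsiness recognition, attention attribution, and feature-geometry diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(drowsecam)
```

## The problem

Drowsiness is visible in a face long before it is reported: the sclera
reddens, the eyelids droop, blinks lengthen. `drowsecam` implements a
frame-level drowsiness classifier over three ways of presenting a face to
a small convolutional network — a `28x28` face thumbnail, a `32x64`
stacked pair of eye crops, and their `32x96` horizontal fusion — together
with the two diagnostic instruments that make such a classifier
interpretable: Grad-CAM attention maps (where does the network look?) and
a feature-geometry statistic we call KNN-Sigma (how well do the learned
features cluster?).

The package is exercised end to end on a parametric synthetic face
generator rather than on video data, so every claim the test suite makes
is about signal that was *planted* and can be checked exactly.

## Input construction

Eye boxes are derived from per-eye landmark extrema: the bounding box of
the landmark coordinates, optionally expanded by a margin fraction per
axis and clipped to the image. Coordinates are 0-based with half-open
`[start, end)` boxes in `(row, col)` order — a convention we fixed since
none is standard across imaging toolkits. Each eye crop is resized to
`16x64` (bilinear, corner-aligned) and the two are stacked vertically,
left eye on top (a recorded convention; the composite is lossless either
way). The fusion input places the `32x32` face thumbnail left of the
`32x64` eye pair: the total size `32 rows x 96 cols` forces horizontal
concatenation, and the face-left order is our choice.

For the gender-signal experiment, a 5-row constant strip is appended
below the eye pair — intensity 0 for male, 255 for female — spanning the
image's full 64-pixel width, giving a `37x64` input. (A 32-wide strip
would leave half the rows undefined; full width is the geometrically
consistent reading.)

Network inputs are rescaled to `[0, 1]`. The input-side batch
normalization makes the classifier insensitive to this affine choice.

## The network

The layer sequence is fixed for all input variants:

```
BN -> Conv 32@5x5 (same, stride 1) + LeakyReLU -> BN -> MaxPool 2x2/2
   -> Conv 64@3x3 (same, stride 1) + LeakyReLU -> BN -> MaxPool 2x2/2
   -> Flatten -> Dense 512 + LeakyReLU -> BN -> Dense 2 -> SoftMax
```

* **Convolution** is cross-correlation (no kernel flip), the universal
  convention of CNN frameworks; parameter counts are agnostic to the
  choice.
* **Same padding** adds `(k - 1) / 2` zeros per edge, so stride-1
  convolution preserves spatial size; only the odd kernels 5 and 3 are
  used.
* **LeakyReLU** uses slope `alpha = 0.3` below zero.
* **Batch normalization** standardizes each channel with batch statistics
  (training) or exponential running statistics (inference). We add
  `eps = 1e-3` to the variance — subtracting it, as one sometimes sees
  written, would reintroduce the division-by-zero the term exists to
  prevent. Per channel there are four parameters: trainable scale and
  shift, non-trainable running mean and variance (momentum 0.99, biased
  batch variance).
* A batch-normalization layer sits *before* the first convolution (12
  parameters = 4 x 3 input channels), exactly as the parameter table
  requires.

`count_parameters()` gives the exact accounting: convolutions contribute
`k^2 c_in c_out + c_out`, dense layers `n_in n_out + n_out`, batch
normalization 4 per channel (2 trainable). For the three canonical inputs
the trainable totals are 1,629,320 (face), 4,217,992 (eye) and 6,315,144
(fusion); grand totals add 1,222 running statistics each. A test
enumerates the concrete weight arrays of every built model and checks the
analytic counts against them.

Weights are initialized with fan-based (Glorot) uniform draws under a
recorded seed; biases start at zero.

### Engine

No deep-learning framework is involved: forward, backward and the SGD
loop are written analytically (Rcpp/RcppArmadillo, im2col + BLAS gemm).
The training loop runs in single precision — the standard arithmetic for
CNN training — while inference and the standalone `conv2d()` primitive
run in double precision, so the exactness oracles (brute-force
convolution at `1e-10`, softmax normalization at `1e-12`) apply
unweakened. A pure-R forward pass composed from the exported layer
primitives (`cnn_forward_reference()`) is kept as an independent route
and must agree with the compiled engine to `1e-10` in the tests.

## Training protocol

Plain SGD (no momentum), categorical cross-entropy, and a staircase
learning schedule `lr = 0.01 * rate^floor(step / 1000)` with decay rate
0.9 for the fusion input and 0.75 for the eye input. The face model's
rate is never specified alongside the others; we default it to 0.75 (the
eye-side value) and flag the assumption in `train_config()`. Training
halts at a hard cap of 10,000 optimizer steps — we read the published
"early stop at 10,000 steps" as a step cap, since no validation split is
described anywhere. Batch size is not part of the recipe; the default is
32 and it is configurable.

Evaluation uses four *independent* stratified 70/30 train/test splits at
the **subject** level: frame-level splitting would leak subject identity
into the test set, which is precisely the face-recognition confound the
attention analysis is designed to expose. (Four resamples of 70/30 are
not a disjoint 4-fold partition; we follow the four-iteration scheme as
described.) Per-class accuracies are reported at the 0.5 operating point;
their unweighted mean is the default "average" (a frame-weighted mode is
available, since published average columns are sometimes one, sometimes
the other). The ROC sweeps every distinct score as a threshold and the
AUC is trapezoidal — equal to the Mann-Whitney concordant-pair statistic,
which the tests verify on random score sets.

## Grad-CAM

For a class `c` with pre-softmax score `y^c` and last-convolution feature
maps `A^k` (we take the convolution's linear output, before its
activation), the channel weights are spatial means of the gradient,

    alpha_k^c = (1/Z) * sum_ij  d y^c / d A_ij^k ,

and the heatmap is `ReLU(sum_k alpha_k^c A^k)`, up-sampled bilinearly to
the input size. Two recorded choices: the attributed score is the
pre-softmax logit (standard practice; a softmax-probability mode is
available behind a flag), and the attributed class defaults to the
predicted one. Gradients are computed analytically by the same R code
path whose forward map the finite-difference tests probe, so the check is
a genuine two-route comparison. Display normalization is per-image
min-max; raw maps are kept for quantitative scoring.

`attention_fraction()` turns the qualitative "the model looks at the
sclera" into a number: the share of heatmap mass inside a region mask,
with the mask's area share as the chance baseline. The classic CAM
formulation (global-average-pooling networks) coincides with Grad-CAM's
alpha weights exactly in that special case and is not implemented
separately.

## Feature analysis

Features are the post-activation outputs of the 512-unit dense layer.
(The alternative reading — the 2-unit output layer — would make a
three-component PCA degenerate, so the wide layer is used; a `layer`
switch exposes both.) PCA mean-centers before the covariance — the
textbook covariance definition, even where a formula omits the centering
— and reports the top three components with descending eigenvalues,
cross-checked against an explicit eigendecomposition in the tests.

**KNN-Sigma.** For each k on a percentage grid (default 1%..100% of
`n - 1`, step 1, matching how such curves are plotted), every point is
classified by majority vote of its *extended* k-neighbourhood: all
points within the k-th-nearest distance, ties included, so the
neighbourhood may exceed k. Recorded decisions:

* **Leave-one-out**: the query is excluded from its own neighbourhood —
  self-inclusion would trivially inflate accuracy at small k.
* **Vote ties** break toward the lower class index, deterministically;
  the tie count is reported.
* The summary statistic is the mean accuracy over the grid. The printed
  normalization one finds for this quantity is not dimensionally
  interpretable; the per-k accuracy curve plus its mean is what the
  accompanying prose and figures describe, and that is what we compute.

Low-k accuracy measures homogeneous concentration (tight within-class
clumps); high-k accuracy measures heterogeneous separation (classes
distinct at large scales). One artifact is worth knowing: with *exactly*
balanced labels, the leave-one-out vote at `k = n - 1` is anti-predictive
(the query's own class is always one vote short), so chance-level
reference curves in the tests use labels with a clear majority margin.

## The synthetic generator

Each subject carries two independent class cues, sclera red excess and
eyelid aperture, drawn from class populations whose means differ by
`effect_size` within-class standard deviations (alert redness
0.10 ± 0.05, aperture 0.80 ± 0.05; drowsy shifted by `effect_size` SDs,
default 3 — a strong, cleanly recoverable signal). The sclera is drawn at
green/blue level 0.5 with the red channel raised by the redness value, so
the red-minus-green pixel mean over the sclera mask reproduces the
parameter on the 0..255 scale — a property the tests recompute from
rendered pixels. Frames add small per-frame jitter (redness SD 0.02,
aperture SD 0.03, ±1 px eye-center jitter) and i.i.d. Gaussian pixel
noise (SD 0.02) before 8-bit quantization. Rendering is deterministic in
`(profile, frame index)`; every stage's sub-seed derives from one master
seed.

Gender is encoded only in the face context — a full-width hair band,
dark for male, light for female — and never in the eyes, so the package
reproduces by construction the finding that gender is recoverable from
face inputs but not from eye inputs, and that a face-context model can
distract itself with identity cues. A `gender_confound = FALSE` switch
renders the band at a fixed mid-grey, confining all structure to the eye
regions (a property the tests assert via per-region pixel means).

What the generator does **not** emulate: real facial texture and pose,
landmark-detector noise (landmarks are exact ellipse extrema), blink
dynamics over time (frames are i.i.d. given the subject, since no
frame-sampling scheme from video is specified), glasses, occlusions, and
illumination changes. Passing the end-to-end suite therefore shows that
the pipeline recovers a planted, well-separated signal — not that it
reaches any particular accuracy on real drowsiness video.

## Desk-scale protocol

The stochastic end-to-end suite runs: 40 subjects x 10 frames at effect
size 3; the eye model trained for 2,000 steps at batch size 8 in each of
the four 70/30 iterations (mean test AUC is required to reach 0.95);
Grad-CAM sclera-attention checked on the first iteration's test frames
(the mass fraction on the sclera must beat its area fraction in at least
80% of frames); and the gender comparison trained for 800 steps per
input. These sizes are the package's reference desk-scale conditions —
small enough to run on one CPU core in minutes, large enough that the
planted signal dominates sampling noise.

## Known limitations

* The engine implements exactly one architecture family; layer widths are
  read from the weight arrays (so reduced toy models work), but the
  sequence is fixed.
* Batch normalization inference quality depends on running statistics
  having converged; evaluating after very few steps gives
  poorly-calibrated probabilities at the 0.5 operating point even when
  the ranking (AUC) is already good.
* KNN-Sigma is O(n^2) in frames; for the frame counts used here that is
  milliseconds, but it will not scale to hundreds of thousands of frames
  without sub-sampling.
* The landmark interface is injected: no face or landmark detector is
  included, by design.
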