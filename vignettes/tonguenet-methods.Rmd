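---
title: "Region-partitioned multi-branch tongue diagnosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-partitioned multi-branch tongue diagnosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguenet)
```

## The diagnostic problem

In Traditional Chinese Medicine (TCM), the tongue surface is read as a map
of the five viscera: the tip reflects the heart and lung, the lateral
margins the liver, the center the spleen, and the root the kidney.
`tonguenet` turns this reading into a reproducible computational pipeline:
given a segmented tongue photograph, it predicts five binary health
statuses (0 healthy, 1 unhealthy), one per organ, always in the canonical
order heart, lung, liver, spleen, kidney.

The package has five coupled parts: a deterministic region partition, a
multi-branch convolutional classifier with average-voting fusion, an
asymmetric loss for imbalanced labels, per-organ evaluation metrics with
Grad-CAM inspection, and a synthetic tongue generator that makes the whole
pipeline testable without clinical data.

## Region partition

`region_bounds(h, w)` computes four crop boundaries from image dimensions
alone:

* region A (tip): the bottom fifth of the image, full width;
* region B (margins): two vertical strips, each a fifth of the width,
  spanning the rows above A;
* region D (root): the top two-fifths of the central 60% column band;
* region C (center): the central band between D and A.

The proportions determine the partition only up to integer rounding. We
fix *round half up* on `h/5`, `2h/5` and `w/5`, and mirror the right strip
edge as `c_right = w - c_left`. With those two choices the four regions
tile the image exactly — every pixel in exactly one region — for **all**
sizes from 5×5 up, which `reassemble_partition()` verifies bit-exactly.
Images smaller than 5 pixels in either dimension are rejected rather than
silently producing an empty region. Coordinates are 0-based with half-open
intervals, rows increasing downward. Region B's two strips are
concatenated left-then-right into a single image so every branch consumes
one array; this also makes horizontal flipping commute with partitioning
(a column flip of the concatenated crop equals the margin crop of the
flipped image).

The row extents of B (whether the margin strips include the bottom-fifth
rows) are not fully determined by the verbal description; we use the
unique non-overlapping tiling, with B ending where A begins.

## The multi-branch classifier

`build_organnet()` constructs up to five convolutional backbones with
fully disjoint parameters: one for the whole image and one per region.
The whole-image backbone feeds four 2-layer MLP heads (the region-A head
has two outputs, heart and lung; B, C and D heads one each), and each
region backbone feeds one head of matching width — ten scalar outputs in
total, each squashed through a logistic to a probability.

For organ $i$ the two paths are fused by average voting,

$$L_i = \tfrac{1}{N}\left(L_{i,\mathrm{full}} + L_{i,\mathrm{region}}\right), \qquad N = 2,$$

and the prediction is unhealthy iff $L_i > 0.5$ (strictly; a score of
exactly 0.5 maps to healthy). Because a 0.5 threshold only makes sense on
probabilities, the logistic squashing is applied *before* averaging; the
alternative (averaging raw logits, then squashing) is a one-line change
but is not what the printed decision rule implies. Single-branch subsets
of the same constructor give the ablation variants: `branches = "full"`
is the whole-image baseline, `branches = "B"` the margin-only liver net,
and for these the "fusion" is the identity on the single available path.

### The backbone

No deep-learning framework is assumed: the package ships a compact CNN
engine in pure R (im2col convolutions on BLAS, exact backpropagation,
AdamW). The default `"tiny"` backbone is a 4×4 non-overlapping patch
embedding followed by two 3×3 convolutions (stride 2 then 1) and global
average pooling — at 64×64 input the final feature maps are 8×8, which is
what Grad-CAM weights. The architecture was chosen for desk-scale CPU
training; the engine's gradients are verified against central finite
differences in the test suite. Deep residual backbones of the kind used
in large-scale studies (101 layers at 224×224 on GPU hardware) are
outside this package's scope; the classifier logic, fusion rule, loss and
evaluation are independent of backbone depth.

## Loss

Training minimizes the asymmetric focal-style loss, summed over organs
and averaged over samples:

$$\mathcal{L} = \frac{1}{N}\sum_{j=1}^{N}\sum_{i=1}^{5}
L_{\mathrm{ASL}}(p_{ij}, y_{ij}), \qquad
L_{\mathrm{ASL}}(p, y) = \begin{cases}
-(1-p)^{\gamma}\log p & y = 1\\
-p^{\gamma}\log(1-p) & y = 0.
\end{cases}$$

With $\gamma = 0$ this is binary cross-entropy exactly; $\gamma > 0$
down-weights confident, easy examples so minority-class errors dominate
the gradient. Note the sign: the two power-weighted log terms must be
negated to give a non-negative quantity that can be minimized. The
focusing exponent defaults to $\gamma = 2$, the standard focal-loss
default, and is configurable; a single $\gamma$ is shared by the positive
and negative arms. Probabilities are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-7}$ before the
logarithms.

During training every one of the ten head outputs is supervised with its
organ's labels (joint training of all branches in one optimizer run);
fusion is used only at inference. This keeps a single training loop and
lets the ablation's single-region networks reuse exactly the same code
path trained in isolation.

## Metrics

Per organ, with unhealthy as the positive class:
accuracy $=(TP+TN)/(TP+TN+FP+FN)$, precision $=TP/(TP+FP)$, recall
$=TP/(TP+FN)$, and F1 the harmonic mean of precision and recall. Macro
averages are unweighted means over the five organs. A zero denominator in
precision or recall yields 0 and sets the `zero_denominator` flag in the
report — a conservative convention that never inflates a score.
Degenerate empty inputs raise errors instead of returning zeros.

## The synthetic cohort generator

The clinical dataset this pipeline targets is not publicly available, so
the generator is a first-class module, not a test shim. It emulates
exactly the structure the pipeline exploits:

* **Labels.** Each organ is an independent Bernoulli draw. The default
  marginals are the reported per-organ unhealthy fractions of a
  4,645-participant clinical cohort (heart 0.453, lung 0.590, liver
  0.633, spleen 0.994, kidney 0.670) — the strong imbalance, with the
  spleen almost always flagged, is a deliberate property of the study
  conditions, not an artifact. Only marginals are reported for the real
  cohort, so no label correlation is modeled.
* **Scenes.** A pink elliptical tongue body with jittered geometry and
  color on a neutral background, additive Gaussian noise
  (`noise_sd = 0.02` in intensity units on [0, 1]).
* **Features.** For every unhealthy organ, 1–3 features from that organ's
  menu are planted strictly inside its diagnostic region: spots and red
  patches at the tip (heart), spots and fur patches in the front band
  (lung), toothmarks and spots on the margins (liver), cracks and fur
  patches in the center (spleen), cracks and pale patches at the root
  (kidney). Heart features are confined to the lower half of region A
  (the tip proper) and lung features to its upper half — the verbal
  description places the heart at the tip but leaves the lung sub-area
  open, and this split keeps the two region-A organs visually separable.
  Toothmarks are drawn as scalloped indentations on the outer edges of
  the margin strips. Every planted feature is recorded in a ledger with
  its bounding box, so label-feature-region consistency is assertable,
  not assumed.

Healthy organs receive no features. All randomness flows from one cohort
seed through per-sample child seeds, making every scene and every cohort
bit-reproducible.

What the generator does **not** emulate: photographic variability
(lighting, pose, occlusion), the 19-feature clinical taxonomy (fur
subtypes are collapsed into one patch renderer), whole-tongue body-color
shifts, label correlations, and annotator disagreement. Passing tests on
synthetic data therefore demonstrate that the pipeline's mechanics are
correct and that region-localized signal is recoverable — not that any
particular accuracy transfers to clinical photographs.

## Training protocol and problem sizes

Defaults follow the reference protocol: AdamW with learning rate 5e-4,
batch size 64, random horizontal flips. Flips are applied to the cached
per-branch tensors; by the commutation property above this equals
flipping the photograph before partitioning, so the margin strips swap
consistently. No learning-rate schedule is used; optional early stopping
on validation macro-F1 (`patience`) is off by default.

The package's test-scale preset is a 2,000-scene cohort at 64×64 with the
tiny backbone and 6 training epochs (chosen once for the preset: the
small network on strongly localized cues converges within a handful of
epochs, and 6 keeps the five-seed ablation protocol comfortably on a
single CPU). The study-scale geometry (4,645 samples split
3,455/295/895 at 224×224) is available as `study_cohort_spec()`.

The ablation protocol trains, under one identical configuration, the
whole-image baseline, the four single-region networks and the fused
model, and tabulates per-organ accuracy/F1 with cells undefined where a
branch does not predict an organ. The acceptance property mirrors the
qualitative finding that fusion beats the whole-image baseline in macro
F1 in the large majority of seeds when cues are region-localized; with
cues scattered uniformly no such dominance is expected.

## Grad-CAM

`gradcam()` differentiates an organ's pre-sigmoid score with respect to
the chosen branch's last convolutional maps, weights each map by its
spatially averaged gradient, rectifies, normalizes the maximum to 1, and
upsamples bilinearly to the branch input grid (renormalizing after
interpolation so the maximum stays 1). An identically zero map — e.g.
from a head with zero weights — is returned as such, and
`cam_region_mass()` flags it rather than dividing by zero. The map is
invariant to positive rescaling of the score.

Localization is quantified on the whole-image branch for the **spleen**
(center region): the mean fraction of activation mass inside region C
over positive test images, compared against C's area fraction (~0.23 at
64×64). The spleen is the organ whose cues the whole-image branch learns
most reliably under the default marginals. Tip-organ maps (heart, lung)
on the whole-image branch typically do *not* concentrate in region A —
the whole-image model misses fine tip cues, which is precisely the
motivation for dedicating branches to regions.

## Numerical choices and degenerate inputs

* Boundary rounding: round half up, so fifth-boundaries are stable and
  parity-independent; `c_right` mirrored from `c_left`.
* Images smaller than 5×5, non-3-channel arrays, probabilities outside
  [0, 1], mismatched shapes, empty splits and empty prediction vectors
  all raise errors with explicit messages; nothing degrades to zeros.
* Loss clamping at $\varepsilon = 10^{-7}$; the training gradient uses
  the same clamped probability.
* The decision rule is strictly `>`; exactly-at-threshold scores map to
  healthy.
* Region crops are resized with bilinear interpolation (aspect
  distortion accepted) to one square input size per model.
* All stochastic steps (weight init, shuffling, flips, label draws,
  scene rendering) derive from explicit integer seeds; single-threaded
  runs are bit-reproducible.

## Known limitations

Synthetic scenes are far simpler than clinical photographs; the tiny
backbone saturates well below clinical-grade accuracy; organ labels are
sampled independently although comorbidity correlations surely exist;
the margin-strip partition is rectangular rather than anatomically
contoured; and no probability calibration is performed. These are scope
boundaries, not defects: the package's claims are about the pipeline's
correctness and the recoverability of region-localized signal.
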