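---
title: "Methods: recognising pulmonary nodule spiculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognising pulmonary nodule spiculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spicnet` recognises the spiculation sign of pulmonary nodules in chest CT
through four stages: sparse-decomposition segmentation, tri-planar
maximum-intensity projection, polar boundary analysis with dynamic time
warping, and a semi-supervised adversarial classifier. This vignette is the
package's own account of the science: the models, the parameters that
matter, the numerical choices, and what the accompanying phantom
experiments do and do not demonstrate.

## Input model and windowing

A CT volume is a 3D field of Hounsfield units in `(z, y, x)` order. Because
nodules live in aerated lung, analysis happens on a lung window: an
explicit interval `[lo, hi]` HU mapped affinely onto `[0, 1]` with
clamping. Clinical window conventions quote a centre/width pair and vary
between scanners, so the window is stored as an explicit interval rather
than a width; the default `[-1350, 250]` HU is a standard lung window of
width 1600, and both bounds are user-overridable. The map is monotone, so
ordering of attenuation values is preserved. Regions of interest are
clipped at volume borders rather than padded — padding would invent HU
values where none were measured.

## Segmentation by morphological component analysis

A nodule-centred image `I` is treated as a sum of morphological
components, each with a dictionary in which it — and essentially only it —
is sparse. Two Parseval-frame operators are used, so synthesis is exactly
the adjoint of analysis *and* a left inverse; both contracts are verified
to 1e-6 in the tests:

* **Cartoon dictionary** (`dict_uwt`): an undecimated, shift-invariant
  Haar cascade with per-level filter pairs normalised so
  `H'H + G'G = I` and circular boundary handling. Piecewise-smooth content
  (the nodule body and its edge) concentrates in few detail coefficients;
  the unthresholded coarse plane carries plateau content.
* **Texture dictionary** (`dict_ldct`): blockwise orthonormal DCT-II
  (default 16 px blocks, 50% overlap) with per-pixel weights
  `1/sqrt(cover count)` making the overlapped system a Parseval frame.
  Oscillatory texture compresses into a handful of coefficients per block.
  The per-block DC coefficient is always suppressed: blockwise-constant
  content is cartoon, not texture, and letting the DCT claim it would pull
  the background plateau into the texture component.

The decomposition minimises the `L1`-relaxed sparse objective with a data
fidelity term and an optional total-variation term on the cartoon. The
solver is block-coordinate relaxation with a linearly decaying hard
threshold (`n_iterations` outer steps, default 50; threshold from
`threshold_start` to `threshold_stop` as fractions of the largest initial
detail coefficient). The TV term is implemented as soft-thresholding of the
cartoon's finest undecimated Haar details by `gamma_tv * threshold`
(default `gamma_tv = 0.1`), the standard light-weight TV surrogate in MCA
solvers. Numerical choices:

* The residual is *defined* by subtraction, so
  `cartoon + texture + residual == I` holds exactly at every iterate.
* A monotone safeguard keeps the best iterate whenever an alternating
  update would increase the data fidelity; the fidelity trace is therefore
  non-increasing by construction, and sustained growth beyond 10% raises a
  divergence error carrying the trace.
* A zero image short-circuits to zero components.

The default 50 iterations suffice for segmentation masks; the
separation experiment in the test suite runs the solver to convergence
(200 iterations) because energy attribution between components continues
to sharpen after the mask has stabilised.

The nodule component `I_o` is rebuilt from the largest-magnitude cartoon
coefficients. The kept fraction is a magnitude quantile
(`keep_quantile`, default 0.8 = keep the top 20%). Keeping only the top 5%
was tried first and discards too much of the edge detail at the 40–60 px
scale of nodule regions, leaving ripple artefacts that destabilise the
watershed markers; 20% retains the nodule's support while still rejecting
background detail.

### Watershed refinement

The gradient magnitude of `I_o` (central differences, one-sided at
borders) is smoothed by grayscale morphological opening then closing
(disc radius 1 — larger discs erase the thin edge ridge), its regional
minima become markers, and a Meyer-style priority flood grows catchment
basins; pixels reached by two basins become watershed lines. Two marker
policies matter:

* `marker_quantile` (default 0.3): only minima in the lowest 30% of
  gradient values seed basins. Shallow ripple minima otherwise spawn
  dozens of spurious regions.
* A second pass merges adjacent basins whose shared boundary has
  below-median mean gradient saliency, collapsing over-segmentation while
  salient edges survive.

The final mask combines threshold segmentation with the watershed
partition: pixels of `I_o` above `threshold_frac` (default 0.3) of the
background-to-peak range form a candidate set; watershed lines cut that
set, so adherent structures separate at their gradient ridge; the
connected component containing the image centre is selected; and the mask
is refined on the *original* intensities — geodesic dilation inside the
image's own threshold set (recovering thin spicules the sparse
reconstruction attenuates, default 10 iterations) followed by trimming to
that set (removing the rim the smoothed reconstruction adds). Selecting
the raw centre basin alone was also tried: basin boundaries systematically
sit half a pixel to a pixel off the true edge, which is a large overlap
penalty at nodule radii of 8–12 px.

Detection failure — rather than an error — is flagged when the candidate
component is missing or smaller than 5 px, when the mask-vs-surroundings
contrast of `I_o` falls below `min_contrast` (default 0.1), or when the
"nodule" swallows more than 60% of the frame; a featureless noise image
therefore yields an empty, flagged mask.

## Tri-planar maximum-intensity projection

`M(x, y) = max` over the slab of slices within `slab_half_depth` of the
nodule centre, computed along each anatomical axis (axial = z, coronal =
y, sagittal = x under the `(z, y, x)` convention — fixed here explicitly
to prevent silent transposition). The slab half-depth defaults to the
nodule radius estimate: deep enough to capture the whole nodule, local
enough that distant bright structures cannot intrude. MIP dominance
(every MIP pixel at least equals every contributing slice pixel), slab
monotonicity, and slice-order invariance are asserted as properties in the
tests.

## Boundary unfolding, protuberances, DTW

Each view's mask is unfolded about the foreground centroid: for each of
`n_samples` (default 360, i.e. 1 degree) clockwise angles — theta = 0
toward +x, quadrant-aware arctangent, clockwise under the y-down image
convention — the radius of the *farthest* boundary crossing is recorded.
Farthest, not nearest: a spicule tip lies beyond the body boundary along
its ray, and the nearest crossing would hide it. The binary mask is
sampled bilinearly at 0.25 px radial steps and the 0.5-level crossing is
located by linear interpolation, giving sub-pixel boundary radii. The
series is rotated so its global minimum — the boundary point closest to
the centre — is index 1, which normalises the start point across rotated
masks; ties take the first minimum.

Protuberance extraction subtracts the series minimum (the baseline) and
keeps maximal contiguous runs exceeding the baseline by more than
`baseline_tolerance` (default 1 px) whose peak reaches `min_prominence`
(default 2 px), honouring circular adjacency. The tolerance exists because
a digital circle's sampled radius wobbles by up to about a pixel; without
it the whole boundary of any real mask forms one run and separate spicules
merge. Stored values remain full heights above the baseline. Runs are
sorted by descending peak prominence and concatenated, axial then coronal
then sagittal; alternative view fusions were considered but concatenation
in a fixed order keeps the series interpretable and the DTW cost additive
over views.

DTW uses the standard recurrence with Euclidean local cost and the
conventional boundary conditions; the local cost pairs `P_i` with `Q_j`
(the cross-index form — pairing equal indices would leave the recurrence
ill-defined for unequal lengths). Classification is k-nearest-neighbour
majority vote (default k = 3, odd so binary votes cannot tie) against a
labelled reference database; a sample with no protuberance anywhere is
non-spiculated by convention with infinite score. A k-NN rule subsumes a
fixed distance threshold while adapting to the database's scale.

## Semi-supervised adversarial classifier

Feature vectors are the concatenated protuberance series resampled to
`feature_len` (default 64) values — smooth nodules give all-zero vectors,
spiculated ones a prominence-ordered sawtooth — rather than raw images:
the upstream stages have already made the class structure explicit, and a
compact feature keeps CPU training in seconds. Both networks are small
MLPs (generator `z(16) -> 64 -> d` and classifier `d -> 64 -> K`, tanh
hidden units, Xavier-scaled initialisation), trained with Adam
(lr 2e-3) by alternating one discriminator and one generator step per
mini-batch.

The discriminator loss is `alpha*L1 + beta*L2 + gamma*Psi` with
`alpha + beta + gamma = 1` (defaults 0.5/0.3/0.2 — supervision dominates,
the adversarial term regularises, the manifold term is a mild stabiliser):

* `L1`: softmax cross-entropy on the labelled subset.
* `L2`: `-E log B(x) - E log(1 - B(x_g))`. For epochs before
  `mode_switch_frac` (default 0.3) of training, `B*` is the logistic of
  the *mean* class activation — independent of the immature classifier's
  class preferences; afterwards the log-sum form `B = Z/(1+Z)`,
  `Z = sum_k exp l_k`, which sharpens a mature classifier. Both are
  evaluated through softplus in log space, so logits of magnitude 1e3
  neither overflow nor saturate to NaN.
* `Psi`: mean squared change of the classifier output under
  `G(z + eps*dbar)` vs `G(z)`, with `dbar` a unit-normalised Gaussian
  disturbance and `eps = 0.1` of the unit latent scale. The step size of
  this term is folded into the optimiser's handling of its gradient
  rather than a separate update schedule. The feature map defaults to the
  softmax output (decision-level robustness); the hidden layer is a
  config option.

The generator minimises mean + standard-deviation feature matching
between real and generated batches (sample standard deviation with `n-1`;
batches of one are rejected since the deviation is undefined). All
gradients are hand-derived and checked against central finite differences
at 1e-5 relative tolerance in the test suite — including the composite
discriminator gradient through both MLPs.

One integer seed drives parameter initialisation, shuffling, latent
draws, and manifold disturbances; the caller's RNG state is saved and
restored, so training is reproducible and side-effect-free. Prediction is
the softmax argmax with ties broken toward the lower class index. When
both a DTW database and a trained model are supplied to the pipeline, the
adversarial classifier decides — it consumes strictly more information
(the full resampled series rather than the DTW score).

## The phantom generator

Phantoms emulate lung-windowed, nodule-centred CT regions: a digital ball
of uniform intensity (default 0.8) on a parenchyma plateau (0.15) with
additive Gaussian noise (sigma 0.04) and a low-frequency cosine texture
(amplitude 0.04) that gives the texture dictionary real work. Spiculated
phantoms add 3–8 tapered radial cones (length 4–8 voxels, basal width 2,
with a ~0.75 voxel width floor so digital spicules stay 8-connected),
azimuths drawn uniformly and elevations within ±15 degrees of the axial
plane; an optional adherent vessel tube is available. The defaults keep
nodule/background contrast above three noise standard deviations, the
regime in which nodules are visually evident, and the generator enforces
that margin. One seed drives a generation-local RNG stream, so datasets
are bit-reproducible regardless of caller RNG state.

What the phantoms do *not* emulate: partial-volume blur at the nodule
rim (phantom nodules have noise-free, uniform interiors), pleural or
vessel attachment geometry beyond a straight tube, ground-glass opacity,
anisotropic voxels, and scanner-specific noise spectra. Passing phantom
tests therefore demonstrates the pipeline's mechanics — separation,
projection, unfolding, warping, training — under controlled morphology,
not clinical-grade performance; the segmentation's boundary-refinement
step in particular benefits from the phantoms' sharp edges.

## Problem sizes in the test suite

The suite generates everything programmatically: 41³ voxel phantoms for
per-slice experiments (odd-sized so the mid-axial plane passes through
the nodule centre exactly), 48³ phantoms for volumetric pipeline runs,
32×32 or 64×64 images for dictionary and separation checks, toy 2D
Gaussian sets of 200 points for classifier training, and an end-to-end
experiment with 40 training and 20 held-out phantoms at half-masked
labels. These sizes are the package's chosen experimental scale: large
enough that every stage operates in its intended regime, small enough to
iterate on quickly.

## Known limitations

* MCA is 2D, per-view; a 3D decomposition might fuse information earlier.
* The watershed merge criterion (below-median boundary saliency) is
  global; heavily cluttered scenes may merge across a genuinely salient
  but locally weak edge.
* DTW is exact dynamic programming without banding; series beyond a few
  thousand samples would benefit from a Sakoe–Chiba constraint.
* The classifier is an MLP over boundary features; it cannot recover
  signs the segmentation/unfolding stages fail to expose.
* DICOM input, HU calibration, and whole-lung nodule *detection*
  (candidate finding) are out of scope; the pipeline assumes a nodule
  centre.
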