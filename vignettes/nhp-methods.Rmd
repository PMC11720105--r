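---
title: "Reproducing natural head position from skull surfaces: models and methods"
author: "nhpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducing natural head position from skull surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhpnet)
```

## The problem

Orthognathic (corrective jaw) surgery is planned against the *natural head
position* (NHP): the upright posture a patient holds when looking at a
distant point at eye level. Cephalometric measurements, osteotomy templates
and symmetry assessments are all defined in this frame, and deviations of
only 1–2 degrees propagate to millimetre-scale planning errors. A CT scan,
however, captures the head in whatever posture the scanner headrest
produced. The task addressed by this package is to estimate, from the skull
surface geometry alone, the rotation that maps the CT-acquired posture back
to NHP.

The estimator is a geometric deep-learning regressor. The skull surface
(extracted from CT by global thresholding and isosurface extraction, or
loaded directly from STL) is converted to a fixed-size point cloud,
normalized into the unit sphere, and passed through a hierarchy of two
set-abstraction blocks, a global max pooling, and a fully connected head
that outputs the nine entries of a rotation matrix. The raw output is
projected onto SO(3) by singular value decomposition at inference time.

## Data model and conventions

All coordinates are millimetres in a right-handed anatomical frame:
+x anterior, +y left, +z superior. Euler angles are degrees, composed as
`R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`; pitch lies in [−90°, 90°], and at
gimbal lock roll is reported as zero with yaw absorbing the free angle.
These conventions are internal choices — angles reported by different
clinical tools are comparable only after mapping to a shared convention —
and every function in the package uses them consistently.

Two quality metrics are used throughout:

* per-angle mean absolute error,
  $\mathrm{MAE} = \frac{1}{n}\sum_i |\hat\theta_i - \theta_i|$, computed
  independently for roll, pitch and yaw, and
* the geodesic rotation error
  $\mathrm{RE} = \arccos\!\big(\tfrac{\mathrm{Tr}(\hat R R^\top) - 1}{2}\big)$,
  the angle of the residual rotation, with the arccos argument clamped to
  [−1, 1] against floating-point error.

The SVD projection returns $U\,\mathrm{diag}(1,1,\det(UV^\top))\,V^\top$
rather than the plain $UV^\top$: for raw matrices with negative determinant
the plain product is a reflection, and the determinant correction makes the
output the Frobenius-nearest *proper* rotation in every case.

## From CT volume to point cloud

Volumes are accepted as NIfTI or as a plain-text array with a JSON header
(`readVolume()`); DICOM parsing is out of scope. Bone is segmented by
inclusive global thresholding ($S = 1$ iff $I \ge T$). No threshold is
universal across scanners; the default of 300 HU is a conventional adult
bone threshold, exposed as a parameter. The isosurface at level 0.5 is extracted by marching a
tetrahedral decomposition of the voxel grid; the binary field is first
lightly box-smoothed (two passes) so that linear edge interpolation places
vertices on an anti-aliased boundary rather than on the half-voxel
staircase — without this, surface-area estimates on phantoms inflate by
about 8%, with it a ball phantom's area is within 2% of $4\pi r^2$. Only
the largest connected surface component is kept, standing in for the manual
speckle cleanup a clinician performs. Meshes are read and written as STL
(both dialects read, binary written; the triangle soup is merged at 1e-6 mm
to recover shared vertices).

Point clouds are sampled area-uniformly (triangle chosen proportionally to
area, position uniform in barycentric coordinates) and normalized by
centroid subtraction followed by division by the maximum centred norm.
2048 points is the reference size; the desk profile uses 512. The centroid
and scale are recorded, so the mapping back to millimetres is exact.

## The synthetic cohort

Clinical CT cohorts with expert NHP annotations are IRB-restricted, so the
package generates skull proxies with *known* ground truth. A proxy is a
star-shaped closed surface (UV-sphere topology, Euler characteristic 2)
whose radius combines three parts: a superellipsoid cranium (semiaxes
80 × 65 × 70 mm, exponent 2.5), a jaw lobe fused anterior-inferiorly
(Gaussian angular lobe toward (60, 0, −55) mm), and a single 6-mm lateral
bump off the midline. The bump breaks left–right symmetry and the jaw
breaks the remaining two axes, so no non-identity rotation maps the shape
onto itself and the canonical orientation is identifiable — with the jaw
and bump switched off the surface is exactly mirror-symmetric, which the
test suite uses as an oracle.

Per-subject variability multiplies lengths (semiaxes, jaw reach, jaw
strength, bump height) by independent Gaussian factors with 10% relative
spread. Directions are deliberately *not* jittered: in this family the
directions are the anatomy that defines the canonical frame, and length
jitter alone already tilts naive template matching by ~5 degrees per
subject (the cranium axes can nearly swap ranks), making the recovery task
non-trivial without making it unidentifiable.

Acquisition misalignment is modelled as independent truncated-normal
roll/pitch/yaw (sd 5° per axis, hard bound 15°) — a plausible magnitude for
head deviation in a CT headrest; both are configurable. The acquired mesh
is the canonical mesh rotated about its centroid by the misalignment; the
stored ground truth is the transpose, i.e. the NHP-restoring rotation the
network must predict, and rotating the acquired mesh by it reproduces the
canonical mesh to machine precision. Generation is bit-reproducible from
one integer seed, including the STL bytes written to disk.

What passing tests on this cohort do *not* show: proxies have no teeth,
sinuses, metal artifacts, or mesh defects, their shape family is
six-parameter rather than anatomical, and the misalignment distribution is
an assumption, not calibrated to any clinical cohort. Results on the proxy
cohort demonstrate that the pipeline can recover planted orientations
through the full mesh-to-rotation path, not that it reaches clinical
accuracy on real skulls.

## Network architecture

Each set-abstraction block (SAB) performs sampling, grouping and
convolution. Farthest point sampling greedily selects centroids maximizing
the minimum distance to those already selected; the start index is fixed at
the first point so sampling is deterministic, and ties break toward the
lowest index. Grouping collects all points within an inclusive radius of
each centroid, keeps the nearest `maxGroupSize` if the group overflows, and
pads short groups by repeating the centroid, so tensors stay rectangular.
The point convolution computes, per centroid,
$f'_i = \sum_{j \in G_i} W(p_j - p'_i)\, f_j / \rho(p_j)$: a two-layer
weight net maps the 3D relative offset to a weight vector, the sum of outer
products between density-corrected features and offset weights is flattened
and linearly projected, and a rectifier is applied. The density
$\rho$ is a fixed Gaussian kernel density over the block's input cloud
(bandwidths 0.1 and 0.2 of unit scale), floored at 1e-8 and normalized to
mean one per cloud — the correction divides out *non-uniformity*, and
fixing its scale keeps feature magnitudes comparable across clouds, which
we found essential for stable optimization. The first block's features are
the raw coordinates; the second block's input features are the first
block's outputs concatenated with the centroid coordinates, so the global
stage can couple what fired with where it fired. Global max pooling over
the remaining centroids and a fully connected head (final width 9,
reshaped row-major) complete the forward pass. No normalization layers are
used: with a batch size of one, batch statistics are degenerate.

The full-scale architecture (SAB1: 512 centroids, radius 0.2, groups of 32,
128 channels; SAB2: 128 centroids, radius 0.4, groups of 64, 512 channels;
head 512-256-9; weight nets of width 16) has 1,476,905 learnable
parameters, reported exactly by `countParameters(networkConfig())`. The
desk profile used by the tests shrinks the widths (SAB1 32 channels, SAB2
288 channels, a single linear head layer) and configures the second block
as a *global* set abstraction: its radius spans the whole unit sphere,
every first-block centroid joins every group, and all 128 centroids are
kept for pooling. This is the classic closing layer of point-set
hierarchies, and it matters doubly here: with a local second block, global
sums of patch statistics can never form before the max pooling (we
measured that whole-object orientation is then not linearly decodable from
the pooled features), and the max over the full centroid set acts as a
directional-extent reader — on this shape family, directional extents
turned out to be the single most informative global statistic for
orientation.

### Initialization

Weights are He-scaled Gaussians with three structured exceptions, all
seeded and all trainable:

* the weight net's first four outputs are initialized to the constant 1 and
  the three linear offset coordinates (linearity passes through the
  rectifier via paired units, $\mathrm{relu}(o) - \mathrm{relu}(-o) = o$),
  so each block starts as a density-weighted extractor of zeroth/first
  local moments;
* the feature projection starts with (a) directional channels — random
  unit directions applied to the density-weighted position entries, which
  after max pooling read out the object's extent along each direction —
  and (b) paired ± selectors of individual aggregate entries, scaled to
  order one by group size and radius, so those moment statistics survive
  the rectifier with known meaning and magnitude;
* the final head bias is the flattened identity matrix, so the untrained
  network predicts approximately the identity rotation and training learns
  a correction.

The rationale is bootstrap speed: with fully random initialization the
pooled global features carry no linearly decodable orientation information,
the head's gradient has near-zero signal at the mean-prediction plateau,
and short training runs never leave it. Starting the convolution stack at
interpretable geometric statistics gives the head a usable gradient from
the first step; a linear readout of the initial pooled features already
ranks well below the no-correction baseline, and training refines from
there.

## Loss functions

The Wing loss is applied elementwise to the nine matrix entries with
$d = |x - y|$: $\omega \ln(1 + d/\varepsilon)$ for $d < \omega$ and $d - C$
otherwise, with $C = \omega - \omega\ln(1 + \omega/\varepsilon)$ making the
two branches meet continuously at $d = \omega$ (the first derivative
intentionally jumps from $\omega/(\varepsilon+\omega)$ to 1 there). The
defaults $\omega = 10$, $\varepsilon = 3$ follow the reference protocol;
the grid $\omega \in \{5, 10\}$, $\varepsilon \in \{0.5, 1, 2, 3, 4\}$ is
exposed for sweeps. The loss is reduced by the *mean* over the nine
elements — whether to sum or average is not dictated by the elementwise
formula; the mean keeps $\omega$ and $\varepsilon$ scale-free in the matrix
size. MAE, MSE and Huber (default delta 1) losses are provided for
comparison. The raw 9-element output is *not* orthogonalized during
training — the loss compares the raw matrix to the ground truth — and the
SVD projection is applied only at inference.

## Augmentation

Training cohorts are enlarged by scaling each subject's ground-truth
roll/pitch/yaw within ±50% (factor 30 by default, turning 90 subjects into
exactly 2700 training samples; originals are replaced, matching that
count). Scales are drawn in antithetic pairs $(s, 2-s)$, so the mean of
every augmented angle equals the original angle *exactly*, not merely in
expectation — this is what makes the cohort's mean angles provably
unchanged, at the cost of requiring an even factor. Augmented meshes are
re-rendered by rotating the canonical mesh by the transpose of the new
ground-truth rotation, so the round-trip property holds for every augmented
sample. A zero original angle never varies (±50% of zero is zero) — a known
degeneracy of relative perturbation. Whether the originals should be kept
alongside the augmentations is a judgment call; replacement is the default
because 90 × 30 = 2700 is the stated total.

## Training protocol

The reference protocol is Adam, initial learning rate 1e-4 halved every 50
epochs, 500 epochs, batch size 1, Wing loss, 2048 points. The desk profile
used by the tests is 512 points, 50 epochs, learning rate 1e-3 halved
every 20 — appropriate for the much shorter schedule — with the
set-abstraction blocks frozen at their structured initialization for the
whole schedule (`featureFreezeEpochs`), so the short run trains the
regression head on fixed geometric features. The freeze is an optimization
safeguard specific to batch-size-1 training: per-sample gradients are
noisy and sign-dominated under the Wing loss, and Adam's
magnitude-normalized steps erode the small structured convolution weights
faster than the head can exploit them — in our measurements, equal-rate
end-to-end training at this scale never left the plateau where the network
predicts the cohort-mean rotation, while the probe-then-(optionally)
fine-tune schedule trains reliably. `featureLrScale` and
`featureFreezeEpochs` expose the schedule for longer runs where full
fine-tuning pays off. Frozen epochs also allow the pooled features to be
encoded once per sample, which makes the desk experiment largely
encoding-bound rather than backprop-bound. Everything stochastic
(parameter init, cloud sampling, per-epoch data order) derives from
explicit integer seeds; two runs with the same configuration produce
byte-identical loss histories. Point clouds are sampled once per training
sample and kept fixed across epochs by default (per-epoch resampling is
available as an augmentation); the learning rate at epoch $e$ (1-based) is
$\mathrm{lr}_0 \cdot 0.5^{\lfloor (e-1)/\mathrm{halveEvery} \rfloor}$; the
final-epoch parameters are the result (no early stopping — with a fixed
schedule and no checkpoint selection rule, the last epoch is the only
defensible choice).

Degenerate inputs are handled explicitly: empty segmentations, zero-area
meshes, coincident point clouds and non-finite losses raise errors rather
than propagating silently; a cloud whose maximum norm exceeds 1 + 1e-6
triggers a warning from the forward pass (the contract is a normalized
input).

## The desk experiment

`deskExperiment()` is the package's end-to-end check: a 120/40
train/test cohort at the default variability and misalignment, the compact
network, 512 points, 50 epochs, and evaluation against the identity
baseline (predicting "no correction", whose rotation error equals the
misalignment magnitude, median ≈ 7° under these conditions). The sizes were
chosen as the largest run that completes comfortably on a single CPU
desktop; `scripts/acceptance.R` reruns it from scratch and writes the
resulting metrics as JSON. The training split is augmented 30-fold — the
reference protocol's factor — inside the experiment; each augmented sample
carries its own independently sampled cloud, which doubles as
sampling-noise regularization (we found this essential: with one fixed
cloud per subject the compact network memorizes the exact point pattern
and transfers nothing to resampled clouds of the same mesh).

## Known limitations

* The proxy cohort's difficulty is set by its shape variability and
  misalignment spread; neither is calibrated against clinical data.
* The Euler-angle axis assignment cannot be validated against external
  tools from geometry alone; only internal consistency is testable.
* Training is CPU-bound R; the full-scale 2048-point, 500-epoch protocol is
  supported but intended for overnight runs, not interactive use.
* The estimator regresses nine matrix elements; quaternion or 6D rotation
  parameterizations are out of scope by design.
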