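---
title: "Deep-learning leaf sequencing on synthetic IMRT cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning leaf sequencing on synthetic IMRT cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Online adaptive radiotherapy on an MR-Linac replans the patient before each
fraction. The slow step is converting a desirable dose distribution into a
*deliverable* step-and-shoot IMRT plan: for each beam, a handful of MLC
apertures (field segments) with monitor-unit (MU) weights. `leafseq` studies
a learning-based shortcut: treat per-beam leaf sequencing as image-to-image
translation. The input is the beam's-eye-view (BEV) 2D dose map of a single
beam; the output is a 6-channel stack of MU-weighted aperture masks. A
conditional adversarial network learns the mapping from prior plans; a
deterministic back end converts predicted channels into MLC control points;
gamma analysis and DVH metrics quantify the result.

Because no clinical dataset or commercial treatment planning system is
available to this package, a synthetic simulator generates cohorts with the
same statistical structure (10 patients x 5 fractions x 11 fixed gantry
angles = 550 per-beam samples at full scale), and an idealized dose engine
is used consistently for both ground truth and predicted plans, so all
comparisons are internally valid.

## Machine and coordinate conventions

The machine model is an MR-Linac-like geometry: 80 leaves of 7.15 mm
projected width stacked along the linac X-axis (57.2 cm maximum extent),
leaf travel along the linac Y-axis (22 cm), diaphragms along X. Patient
axes: `x` lateral, `y` anterior-posterior (the beam axis at gantry 0), `z`
superior-inferior. The gantry rotates about `z`; the linac Y-axis coincides
with patient `z`, so aperture images have rows along linac X and columns
along linac Y. All 2D rasters span the full field (572 x 220 mm) so dose
maps and aperture masks are spatially registered pixel-for-pixel. One
constant (`rot_z`) fixes the rotation sign; `rotate_to_bev()` rotating by
the negative gantry angle aligns the beam axis with grid axis 2, and a
rotational-equivariance test pins the convention down.

## The synthetic simulator

`sample_phantom()` builds an ellipsoidal body with an ellipsoidal PTV near
the center and four OARs chosen to exercise DVH comparisons: a duodenum-like
shell abutting the PTV, two kidney-like lateral ellipsoids, and a cord-like
posterior cylinder. OARs never overlap the PTV by construction.

`sample_segment()` draws apertures roughly conformal to a randomly perturbed
ellipse about the PTV's BEV footprint, with smooth per-row edge noise. A
post-pass scales the per-row center/half-width motion so that neither leaf
edge moves more than two leaf widths between adjacent rows; this guarantees
connected, deliverable shapes, which the test suite verifies over 1000
draws. MU weights are drawn log-uniformly on [20, 200] MU — the source
study reports no MU distribution, so this range is this package's own
declared choice, as are all phantom geometry parameters. Plans use the
fixed 11-angle set (5, 25, 60, 90, 155, 175, 195, 260, 290, 310, 345
degrees) and 1-6 segments per beam by default: clinical plans reach 12
segments, but the model emits 6 channels, so the simulator's default stays
within the representable range (the preprocessing layer offers an
error-or-merge policy for overflowing beams).

Fractionated plans of one patient share a plan *structure*: per-beam
segment counts and base aperture shapes come from a per-patient structure
seed, while aperture positions jitter by up to 20% of the target footprint
and each segment's MU by x0.8-1.25 per fraction. This emulates daily
online replanning, where every fraction's plan is a re-optimization of the
same reference plan — which is precisely why keeping one fraction of the
held-out patient in training teaches the model to replan that patient. If
instead every fraction drew an independent structure, the number of real
(versus zero-padded) channels would be unpredictable from the dose map
alone and the learning task would be ill-posed. Delivery order — and hence
channel order in the target stack — is defined as MU-descending, the order
a treatment planning system would plausibly emit; a reproducible ordering
is what makes channel identity learnable at all.

The dose engine is an idealized attenuated back-projection: each beam's
MU-weighted aperture sum is blurred with an isotropic Gaussian penumbra
(sigma 3 mm), projected through the body along the beam axis with
exponential attenuation (mu = 0.005/mm inside the body, zero outside), and
rotated to the gantry angle about the isocenter. It is deterministic and
exactly linear in MU. It deliberately omits scatter, heterogeneity, MLC
transmission and tongue-and-groove effects; it is a stand-in whose only job
is to make the learning task and its evaluation well-posed and
self-consistent. Consequently, passing tests show that the *pipeline*
works, not that the model would reach any particular accuracy on clinical
Monte Carlo dose.

## Preprocessing

For each beam: extract the per-beam 3D dose, resample to the planning grid,
shift the isocenter to the rotation center, rotate to the BEV, sum along
the beam axis, embed in the field raster, resample to 128 x 128 and rescale
to [0, 1]. The removed maximum is kept as `scale`; aperture stacks keep a
`mu_scale` so absolute dose and MU are recoverable — the normalization
bookkeeping is a design choice this package makes explicit. Training sets
share one dataset-level `mu_scale` (the cohort's maximum segment MU), so
channel intensities encode absolute MU and sequencing a prediction needs
no plan-specific scale; a genuine replan could not know the test
fraction's own scale. Targets rasterize each segment's leaf intervals (ones in
the open field), multiply by normalized MU, order channels by delivery
order and zero-pad to 6 channels. `beam_bev_map()` computes the same BEV
map directly in the beam-aligned frame, skipping two rotations; it
correlates with the full chain at r > 0.999 and is what the training-pair
builder uses. Projection is parallel (no divergence correction), matching
the summation definition of the BEV map.

Training pairs are rasterized over the planning grid's BEV extents —
the scale of the planning image — rather than the full machine field: the
dose map the model sees is defined on the daily planning grid, and the
field grid enters only at the sequencing step. Aperture stacks carry
their raster extents so the sequencer can map any raster onto the leaf
grid; full-field rasters remain the default elsewhere and in the
sequencing fixed-point tests.

The well-posedness of the whole idea — that the BEV dose map of a beam
looks like its MU-weighted aperture sum — is made quantitative: on a 64^3,
3 mm grid the mean Pearson correlation across a plan's 11 beams is about
0.96. Attenuation contributes essentially nothing to the residual
decorrelation (setting mu = 0 changes r by < 0.001); the gap comes from
body chord-length variation across rays, a real effect the 2D
approximation ignores.

## The network

The generator is a U-Net: 6 down-sampling blocks (4x4 convolutions, stride
2, instance-style normalization, leaky ReLU 0.2), mirrored transposed
convolution up-sampling blocks (normalization, ReLU) with skip connections,
dropout 0.5 on the first three up blocks as the stochasticity source, and a
6-channel tanh output head: images live in [-1, 1] inside the network, so
the background of an aperture stack sits on the saturated lower rail and
stays crisp — essential here, because the sequencing threshold is
*relative* (2% of each channel's maximum) and would amplify any residual
background noise into spurious apertures. Predictions are mapped back to
[0, 1] and clipped at zero at inference, where dropout is disabled. With
batch size 1, batch
normalization degenerates to instance normalization, which is what is
implemented; bottleneck layers at 1x1 spatial size skip normalization. The
discriminator is a 70x70-receptive-field patch classifier on the dose map
concatenated with a real or predicted stack, with spectral normalization
(one power iteration per step) on all its convolutions; it outputs a patch
grid of logits, never a scalar.

Losses: the discriminator minimizes binary cross-entropy of its patch
scores against soft labels (real in [0.8, 1.2], fake in [0, 0.2], swapped
with probability 0.05 — the sub-ranges within the reported [0, 1.2] span
are this package's choice); the generator minimizes the adversarial
cross-entropy plus `lambda_l1 = 100` times the mean absolute error. The
learning rate defaults to 2e-4 (beta1 = 0.5): the source study states two
inconsistent values (1e-3 and 1e-4), so the standard value for this
architecture family is the default and both alternatives are reachable via
`train_config()`. Everything — initialization, shuffling, dropout, labels —
derives from one seed, and training is bit-reproducible.

There is no autodiff framework in this stack, so all backpropagation
(im2col convolutions, transposed convolutions, normalization, the
spectral-norm chain rule, and the discriminator-to-generator input
gradient) is hand-derived; the test suite checks every path against finite
differences at 1e-4 relative tolerance.

## Leaf sequencing

Predicted channels pass a 2% intensity threshold (relative to the channel
maximum), the MU weight is the channel maximum (all surviving pixels forced
to it), the row axis is resampled to the 80 leaf rows, and each row opens
from its first to its last open pixel — interior holes are bridged, since a
single leaf pair cannot make two openings. Closed rows park at the field
edge; diaphragms take the bounding box of open rows; positions are
quantized to 0.1 mm. Channels empty after thresholding are dropped; a beam
losing all segments is an error by default (a replan must not silently
lose a beam), with a `"keep"` mode for evaluating deliberately bad
baselines. On ground-truth stacks this back end is lossless: re-rasterized
masks are bitwise identical and MUs exact, which cleanly separates
sequencing error (zero) from prediction error.

## Gamma analysis

3D gamma with 3%/3 mm, global normalization to the reference maximum, and a
5%-of-maximum dose threshold; the reference is always the ground-truth
dose. The optimized search enumerates offsets within 3x the distance
tolerance on a sub-voxel lattice (1/10 voxel by default), sorted by
distance and pruned exactly (the distance term alone bounds gamma from
below), so it is provably identical to the exhaustive search; a separate
unpruned brute-force routine serves as the oracle, and equality within
1e-6 is asserted over random dose pairs. An optional cap bounds reported
gamma values (and hence the search) — any cap above 1 leaves pass/fail
untouched; evaluation of grossly wrong baseline plans uses cap 2 with
1/5-voxel stepping for speed. DVHs use 1-unit cumulative bins; percent
differences are `100 * (gt - pred) / gt`, so negative values mean the
prediction exceeds the ground truth.

## The scaled learning study

`scaled_learning_study()` is the package's end-to-end demonstration at
desk scale: 7 patients x 4 fractions (308 beams), 64 x 64 rasters, a
48-voxel 4 mm grid, 35 epochs, width-12 networks, one
leave-one-patient-out fold whose training set keeps the held-out patient's
first fraction (the replanning prior). The study trains with the 1e-3
Adam rate the source protocol reports reaching stability with — at a
reduced epoch budget the output head must reach its saturated
(crisp-background) regime, because the downstream 2% relative threshold
amplifies any residual background into spurious apertures. The trained
model's sequenced plans are compared with an identically built untrained
model on the held-out fractions by mean plan-level gamma passing rate
(3%/3 mm, 5% threshold, cap 2, 1/5-voxel stepping). These problem sizes
are the package's declared study conditions for a CPU-scale run; the
claim tested is directional (trained beats untrained by a wide margin),
not the absolute clinical passing rates of the source study, which are
out of reach without clinical data and a Monte Carlo engine.

## Numerical choices and degenerate inputs

* Trilinear/bilinear interpolation everywhere, zero fill outside grids;
  integer-voxel shifts and 90-degree rotations are exact.
* All-zero dose maps normalize to zero with `scale = 0` flagged rather
  than dividing by zero.
* Zero-radius aperture targets degenerate to a single minimal-opening row;
  fully closed segments are rejected (open plans only).
* Pixel-center membership defines rasterization; recovered leaf edges sit
  on pixel boundaries, which is what makes sequencing a fixed point on
  raster-aligned masks despite the 0.1 mm output quantum.
* Dose volumes round-trip through an RTDose-style scaled quantum
  (`max / 32768`); plan JSON preserves positions to 0.1 mm.

## Limitations

The simulator's anatomy is ellipsoids, its dose engine ignores scatter and
heterogeneity, fraction-to-fraction anatomical change is limited to
aperture/MU resampling, and plans are serialized as RTPlan-like JSON (with
the full control-point semantics) rather than binary DICOM, since no DICOM
library is part of this R stack. Results on this synthetic world measure
pipeline correctness and learnability, not clinical performance.
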