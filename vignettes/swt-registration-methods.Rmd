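---
title: "Rigid CT/CBCT registration with wavelet gradient images and weighted NMI"
author: "swtreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid CT/CBCT registration with wavelet gradient images and weighted NMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swtreg)
```

## The problem

In image-guided radiotherapy a setup cone-beam CT (CBCT) acquired at the
treatment machine must be aligned to the planning CT before each fraction.
For a single axial slice the correction is rigid: two translations and one
in-plane rotation, (dx, dy, theta). Intensity-based registration scores a
candidate alignment by the normalized mutual information (NMI) of the joint
gray-value histogram. NMI sees only the intensity co-occurrence statistics;
it carries no information about *where* gray values sit, which makes it
sensitive to interpolation effects and to the noise and contrast drift
typical of CBCT.

This package supplements the intensity NMI with the NMI of *gradient
images*: companions of the inputs that contain only edge structure, where
tissue transitions are, i.e. exactly the spatial information that the
intensity histogram discards.

## Gradient images from the stationary wavelet transform

The stationary (undecimated, à-trous) wavelet transform decomposes an
image into an approximation band `A_j` and three detail bands (LH, HL, HH)
per level without downsampling: every band keeps the image's shape, and
the transform commutes with translations. Analysis at level `j` is
separable stride-1 correlation with the filter dilated by `2^(j-1)`
(zero-insertion between taps); synthesis applies the adjoint of each
analysis operator with a 1/4-per-level normalization (the average over the
redundant phases). For an orthonormal quadrature-mirror pair this inverts
the analysis exactly at every frequency, so reconstruction is exact to
round-off — a property the test suite asserts at 1e-8 for haar and db2–db8
at depths 1–4.

The **gradient image** is obtained by decomposing to depth 3 (the package
default), zeroing the approximation (low-frequency) band produced at every
level, and inverse-transforming the remaining detail bands. The result is
a signed, zero-mean, edge-dominant image. By linearity it equals the input
minus the approximation-only reconstruction, which the tests verify
directly. Adding a constant to the input leaves the gradient image
unchanged, so global contrast offsets (common in CBCT) do not move the
gradient term at all.

```{r gradient-example}
img <- makePhantom(phantomSpec(shape = c(128, 128), seed = 1))
g <- synthesizeGradientImage(img, levels = 3)
c(mean(pixels(g)), range(pixels(g)))
```

**Wavelet family.** Haar (db1) is the default: the shortest support gives
the sharpest edge localization and the cheapest transform; db2–db8 are
available.

**Boundary handling.** Two modes are provided. `periodic` wraps indices
circularly and makes the transform exactly shift-equivariant — the mode
used by the equivariance tests. `symmetric` (the default for
registration) reflect-extends the image to (2M, 2N) and runs the periodic
transform on the extension, which avoids wrap-around ghost edges between
opposite image borders while keeping reconstruction exact; bands are
stored internally on the extended domain and cropped by the accessors.

## The similarity measure

With marginal entropies `H(A)`, `H(B)` and joint entropy `H(A,B)`
(base-2, from a 64-bin equal-width joint histogram over each image's
frozen gray range), the measure uses

- mutual information `I(A,B) = H(A) + H(B) - H(A,B)`,
- normalized mutual information `NMI(A,B) = (H(A) + H(B)) / H(A,B)`,
  which lies in [1, 2] and tolerates changes in the overlap area.

The intensity NMI (`NMI_i`) and the gradient NMI (`NMI_g`) are fused by a
logistic weight

```
NMI = f(v) * NMI_i + (1 - f(v)) * NMI_g,
f(v) = 1 / (1 + exp(-(v - 0.5) / T)),   v = (x + y) / 2,
```

with temperature `T = 0.04`. Near alignment (both NMIs high) the weight
moves to the intensity term; far from alignment it moves to the gradient
term. The combination is convex, so it is always bounded by its two
inputs.

**The v-scale decision.** The logistic is centered at 0.5, but NMI lives
in [1, 2]: feeding raw NMI into `v` saturates `f` at essentially 1 and
collapses the measure to `NMI_i` alone. The package therefore uses
`x = NMI_i - 1`, `y = NMI_g - 1` inside `v` by default (mapping [1, 2]
onto the logistic's [0, 1] design domain) while mixing the raw NMI values
in the combination itself; `measureConfig(nmi_rescale = FALSE)` restores
the literal saturating behavior for comparison. This was the one genuinely
open design point in the measure, and the rescaled form is the only one
under which the weighting does anything.

**Histogram details.** 64 bins balance bias and variance at the 256²–512²
sample sizes used here. Bin ranges are frozen per image at registration
start so the objective stays smooth across iterations; out-of-bounds
samples of the transformed floating image are excluded (the overlap-only
convention NMI is designed for); gradient images, being signed and
near-zero-mean, are affinely mapped to [0, max reference gray] once before
histogramming so that equal-width bins resolve their distribution.

## Transform and resampling conventions

Pixels are addressed on a 0-based lattice, x along columns, y along rows;
the physical pixel size (mm) rides along in the `Image2D` container. The
forward rigid map is `q = R(theta) (p - c) + c + (dx, dy)` with the
rotation center `c` at the image center `((M-1)/2, (N-1)/2)`. Angles are
degrees. Floating images are pulled back onto the reference grid through
the inverse map with bilinear (default) or nearest interpolation, so each
objective evaluation costs one interpolation pass per image.
Out-of-frame samples get the image minimum (air), or NA markers when the
caller needs to exclude them from histograms. CBCT frames are first
resampled onto the CT grid (physical centers aligned, content magnified by
the spacing ratio, e.g. 1.27/1.17).

## Optimization

Powell's direction-set method with Brent line searches maximizes the fused
measure (by minimizing its negation) over (dx, dy, theta). Defaults:
parameter scales (1 px, 1 px, 1 degree), line-search tolerance 1e-3
scaled units (well below a pixel, consistent with subpixel recovery),
relative objective tolerance 1e-5, at most 50 sweeps, golden-ratio
auto-bracketing from a 1-unit step. The sweep trace is recorded and is
non-increasing by construction; candidates whose overlap with the
reference degenerates are scored with the worst possible measure (NMI = 1)
rather than raising, so line searches can pass through them. Everything is
deterministic.

**Two-stage initialization.** The gradient NMI is short-ranged: its
attraction basin extends roughly over the support of the edge responses,
and the logistic weight hands the fused measure to the gradient term
precisely when the images are far apart. On piecewise-constant scenes the
fused objective is therefore nearly flat at large misalignment, while the
intensity NMI retains long-range attraction. The driver consequently
optimizes the intensity NMI first and then refines the fused measure from
that optimum — the gradient term acting as the precision criterion near
alignment, which is its design role. Both stages use the same optimizer
settings; `mode = "mi_only"` skips the second stage and all gradient
computation, and serves as the baseline comparator.

Misalignments far beyond the capture range (tens of pixels) are handled
the way a therapist would: a manual narrowing translation
(`initial_shift`, in mm) is applied once before optimization, mirroring
the large fixed pre-shift used when CBCT and CT frames start ~80 mm
apart.

## The synthetic phantom

`makePhantom()` emulates an axial CT slice: an elliptical body outline on
an air background filled with randomly placed elliptical and rectangular
"organs" of distinct gray levels (100–1000), so region boundaries include
both curved and straight edges and the gradient image is non-trivial. A
0.7-px Gaussian blur emulates the scanner point-spread/partial-volume
effect (set `blur_sigma = 0` for strictly piecewise-constant output);
`contrast_offset` and additive Gaussian `noise_sigma` are applied last.
`makeCbctLike()` derives the setup-image counterpart: the scene resampled
to a 1.27 mm grid with a contrast offset and noise. Generation is
deterministic given the seed.

What the phantom does *not* emulate: CBCT scatter/cupping artifacts and
streaking, soft-tissue texture, HU calibration differences beyond a global
offset, and anatomy change between scans. Passing the recovery and
linearity protocols here demonstrates the correctness and conditioning of
the pipeline on controlled scenes, not clinical accuracy on patient
images.

## The two evaluation protocols

**Preset recovery.** Ten preset transforms (translations up to 30 px,
rotations between -5 and 2 degrees; see `recoveryPresets()`) are applied
to a noiseless 256x256 phantom; the registration must recover each preset
(as the inverse of the optimized correction). The acceptance suite
requires every error below (0.5 px, 0.5 px, 0.2 deg); measured errors are
on the order of 0.01 px / 0.05 deg. The preset angles are treated as
degrees everywhere: values like -5 or 25 would be absurd setup rotations
in radians.

**Shift linearity.** A CBCT-like floating image is shifted by 80–100 mm
in 5 mm steps along one axis (with 80 mm on the other), the fixed
narrowing pre-shift of (-80, -80) mm is applied, and each shifted copy is
registered. The recovered translation must be linear in the preset shift
(least-squares slope -1, R² at least 0.99) with recovered rotations below
0.5 degrees — the noise is set to 5% of the scene's dynamic range. A
paired comparison over 20 noise realizations of a fixed misalignment
(18, -8, -3.45 deg) additionally requires the fused measure's mean
translation error not to exceed the intensity-only mode's. The rotated,
generic preset is used for this comparison because integer lattice-aligned
shifts make both modes share a half-pixel interpolation bias that would
mask any difference between them.

Problem sizes in the shipped tests and in `scripts/acceptance.R` (256x256
phantoms, 10 + 10 + 40 registrations, 50-image reconstruction sweeps) are
chosen so the complete validation runs in a few minutes on one core.

## Numerical notes and limitations

- Degenerate inputs: constant images have zero detail bands and an
  undefined NMI (joint entropy 0); the measure raises on fully constant
  overlap, and the driver maps degenerate candidates to the worst score.
- Exact zero MSE after recovery is only attainable for integer
  translations under nearest interpolation; bilinear resampling leaves a
  small smoothing residual at region boundaries.
- The optimizer is local. The capture range is set by the intensity NMI
  (roughly ±30 px / ±10 deg on these phantoms); larger offsets need the
  `initial_shift` mechanism.
- 2D only, rigid only: multi-frame volumes, deformable or multiscale
  schemes are out of scope.
- Runtime is dominated by the per-candidate resampling of the intensity
  and gradient images (two passes per evaluation in proposed mode) — the
  known cost of computing two mutual-information terms per iteration.
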