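---
title: "Volume rendering from serial sections: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume rendering from serial sections: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectionvr)
```

## The problem

A serial-section stack is a block of voxels assembled from physically cut,
individually stained, individually photographed slices. Unlike tomographic
data, each slice carries its own coordinate frame and its own staining
state, so three artifact classes dominate: rigid misalignment between
consecutive slices, smooth geometric distortion of each slice (paraffin wax
sections stretch unevenly; resin sections barely at all), and slice-to-slice
staining variation, including progressive bleaching in historical material.
`sectionvr` implements a full pipeline from slice images to
emission–absorption volume renderings, in grayscale via colormaps or in the
true colors of the histological stain, with each manual step of the
classical workflow replaced by a scripted, seeded, testable operation.

This vignette records the models behind each stage, the parameters that
matter, and the design decisions taken where the problem left genuine
freedom. No empirical claims are made here beyond what the package's test
suite and acceptance script compute.

## Conventions

All voxel data are 8-bit per channel. Every operation evaluates in double
precision and quantizes once at its boundary by *round to nearest, ties
away from zero, clamp to [0, 255]*; filters quantize only once at the very
end of their internal iteration. Coordinates are x = column, y = row,
z = slice, 0-based, origin at the image top-left; regions of interest are
half-open. Spacing `(sx, sy, sz)` is in micrometers and supplied by the
user; `sz` is the section thickness. The anisotropy validator enforces
`sz / max(sx, sy) <= 3` (inclusive, because the protocol bound is
"did not exceed"); the classic semithin-resin setting
`0.25 x 0.25 x 0.5` µm gives ratio 2.

## Preprocessing

**Inversion** maps color channels `v -> 255 - v` (alpha excluded) and flags
the stack. Dark-background data are what volume viewers and the luminance
alpha construction expect; a snapshot can be re-inverted at the very end to
recover the stain's bright-field appearance.

**Background normalization** estimates a white point per slice and channel
as an upper percentile (default 0.95 — robust against small dark
foregrounds, the reason a percentile replaces a manual white-point picker)
and linearly rescales values above a preserved dark anchor (the slice's 1st
percentile) so the white point maps to 255. Constant slices pass through
with a warning. The operation is idempotent up to rounding.

**Stain equalization** classifies foreground as luminance below 0.9 of the
slice white point, then applies one multiplicative gain per slice so its
mean foreground luminance matches the stack-wide median of slice
foreground means. Gains are returned and logged. The estimator presumes the
underlying foreground brightness varies slowly along z; on a z-uniform test
object it inverts applied gains to within a few per mil, which is how the
test suite checks it.

**Downsampling** is exact area averaging (integral-image implementation,
arbitrary factors ≥ 1), in-plane only — its purpose is to meet the 3:1
thickness rule, and z is never resampled.

**Despeckling** (default off) replaces the manual retouching of dust and
staining precipitates: background-classified pixels are replaced by a small
median filter; foreground structure is never touched.

## Rigid alignment

The registration objective is the mean squared gray-value difference
between a fixed slice and the rigidly resampled moving slice over their
overlap (color slices are compared on NTSC luminance). The optimizer is an
exhaustive integer-step grid over `(theta, tx, ty)` at the coarsest level of
a factor-2 image pyramid, refined per level by Nelder–Mead — chosen because
the SSD landscape of striped histological content is multi-modal and
derivative-free search is robust to it. If refinement ever ends above the
identity objective, the identity is returned, so a fit is never worse than
doing nothing; constant images return identity with a warning.

Two estimation-only refinements address a subtle failure mode: bilinear
resampling blurs an image by an amount that depends on the sub-pixel phase
of the transform, and a squared-difference objective between
differently-blurred copies is biased by that mismatch. First, both images
are presmoothed (Gaussian, default 2 px) before matching, so the
interpolation blur is small relative to the matching scale. Second, the
final polish minimizes a *symmetric* form of the objective in which both
images are resampled by half the transform (fixed backward, moving
forward), balancing the interpolation blur between the two sides; this
reduces the worst-case rotation bias on strongly jittered pairs by an
order of magnitude. The returned transform always refers to the original
images. Without these, per-pair biases of a few hundredths to tenths of a
degree accumulate into visible rotation drift across a long stack.

Stack alignment proceeds sequentially: each slice is registered to its
aligned predecessor, with the relative transform estimated between the
original slices (equivalent in the continuum, but it avoids resampling the
reference a second time) and composed cumulatively; each slice is then
resampled exactly once. Drift is not redistributed — there is no global
bundle adjustment, matching the sequential workflow the pipeline automates.
Rotation is about the image center. A per-slice transform table is written
as TSV and can be edited and re-imported as manual overrides, replacing the
check-by-eye-and-correct step of the interactive tools. Out-of-bounds
pixels take the fill value: 255 for non-inverted stacks (white background)
and 0 for inverted ones, so exposed corners blend into the background. The
default search range (±15 px, ±10°) is a configuration value, not a claim
about any particular dataset.

Two caveats the tests make explicit: transform recovery is only
well-defined on content whose registration optimum coincides with the
ground truth — the recovery tests therefore use a z-uniform phantom
(adjacent clean slices identical), while on realistic content with
through-z structure the MSD optimum legitimately shifts away from the
ground-truth transform by a few tenths of a degree; and rigid alignment
cannot remove elastic distortion or staining variation, which is visible as
the residual floor in the alignment table.

## 3D filtering

**Gaussian smoothing** is separable convolution per axis with a sampled,
truncated, normalized kernel, symmetric (reflective) boundaries, operating
in voxel units (the kernels are specified in voxels despite anisotropic
spacing; an optional physical-units reading would rescale σz by `sx/sz`,
but the voxel-unit reading is the default because that is how the filter
parameters are conventionally quoted). Defaults: 6×6×6 σ = 1 for paraffin
material, 3×3×3 σ = 1 as the modest option for resin. Even kernel sizes
have no center voxel and are promoted to the next odd size with a notice,
avoiding a half-voxel phase shift while keeping the nominal size in the
configuration.

**Edge-preserving smoothing** is interpreted as Perona–Malik-type nonlinear
diffusion: `u <- u + dt * div(g(|grad u_sigma|) grad u)` with conductance
`g(m) = exp(-(m/contrast)^2)` computed from the Gaussian-presmoothed field
(scale `sigma`, truncation radius `min(ceil(2*sigma), fit-to-volume)`),
face conductances averaged from voxel conductances, zero-flux boundaries.
`contrast` is the gray-value edge threshold: gradients well below it
diffuse freely, gradients above it stall, which is exactly the "smooth but
keep edges" behavior the parameters describe. The published parameter
quadruple (contrast 3.5, sigma 3, step 5, stop 25) is read as: conductance
updated every `step` time units, `floor(stop/step) = 5` updates in total.
This reading of a proprietary filter is an interpretation, not a
reproduction; `step` could alternatively be an iteration count, and the
configuration accepts either reading by adjusting `step`/`stop`.

A numerical point worth recording: an explicit diffusion step of size 5 is
far above the 3D stability bound (`dt <= 1/6` for conductance ≤ 1), so each
outer step is integrated internally with sub-steps `dt <= 1/6` under the
frozen conductance field. This keeps the scheme contractive and preserves
the maximum principle (output range never exceeds input range), which the
test suite asserts, and converges to ordinary Gaussian-like smoothing as
`contrast -> infinity`.

**Color stacks** are split into R, G, B, filtered independently with
identical parameters, and recombined; the alpha channel is recomputed from
the filtered channels by NTSC luminance, so recombination automatically
yields the linear transparency function with no manual adjustment.

## Transparency and colormaps

Stored alpha is 8-bit; the renderer converts to opacity at sampling time.
Four parametric families map alpha to opacity, all monotone with fixed
endpoints `f(0) = 0`, `f(255) = 255`:

- `linear_gamma`: `255 * (A/255)^gamma` — gamma 1 is the linear function,
  gamma > 1 softer, gamma < 1 harder;
- `threshold`: `255 * (A > t)` (strict) — a very hard rendering with
  completely opaque object voxels;
- `power_increasing`: `A^x / 255^(x-1)` — much softer than linear;
- `power_decreasing`: `255 - (255-A)^x / 255^(x-1)` — harder than linear,
  softer than threshold;

plus monotone piecewise-linear control points as the curve-editor
equivalent. The demonstrated exponent x = 3 is the default; any real
x ≥ 1 is accepted. Both colormaps and transfer functions can be inverted
(entry `i -> 255 - i`, `f(A) -> f(255 - A)`), which renders non-inverted
stacks exactly as their inverted counterparts — the test suite checks this
equivalence through the renderer.

The built-in "glow" colormap is a black → dark-red → orange → pale-yellow →
white ramp with non-decreasing luminance and the top 16 entries flattened
to prevent glare at the bright end. Its exact control points
(`(0,0,0), (128,0,0), (255,128,0), (255,255,128), (255,255,255)` at equal
spacing) are a documented package convention — the classical ramp of this
name ships in binary form only, so these anchors are this package's own
definition of the family. The grayscale default pairs glow with gamma 1,
the "almost linear" convention.

## Rendering

Orthographic ray casting in physical coordinates: each pixel casts a ray
along the view direction, samples RGBA trilinearly (nearest-neighbour mode
exists for oracle tests) at `sample_step` µm, converts alpha to opacity
with the step-size correction `a' = 1 - (1 - A/255)^(step/ref)` where
`ref = min(sx, sy, sz)` — this makes accumulated opacity invariant to the
sampling rate on homogeneous volumes — and composites front-to-back with
the over operator, terminating at accumulated opacity 0.995 (standard
practice; invisible at 8-bit output). The background color is blended only
after ray exit, so ROI cropping exposes interior structure rather than
filling it with background. Perspective projection, lighting and shading
are deliberately absent: the model is pure emission–absorption. Turntable
sequences are emitted as numbered frames; video encoding is out of scope.

## The phantom generator

The phantom emulates what the pipeline assumes about real section series,
not the physics of staining. The clean volume rasterizes simple "stained
tissue" primitives (ellipsoids, tubes, shells, boxes) in listed order onto
a white background. The default specimen is a 64×64×40 stack at
`(1, 1, 2)` µm: an elliptical body wall, pale interior, an ellipsoidal
organ, two ducts, and fourteen darkly stained nuclei columns laid out on a
fixed golden-angle spiral. It is mostly z-uniform — adjacent real sections
a few micrometers apart are nearly identical — and deliberately
non-rotation-symmetric, so that slice rotation is identifiable from
content.

Each slice is then degraded, in order: a band-limited elastic displacement
field (coarse-grid Gaussian noise, bilinearly upsampled, scaled to RMS
amplitude); a rigid jitter drawn from `N(0, sigma_t)` per translation axis
and `N(0, sigma_theta)` for rotation; a multiplicative stain gain
`N(1, sigma_g)` on pixel values (what the equalization estimator inverts);
a cumulative bleach factor `(1 - rate)^i` fading stain saturation toward
white (a deliberately different mechanism from gain); and dark salt
speckles. Defaults: `sigma_t = 2` px, `sigma_theta = 1°`, elastic amplitude
1.5 px at smoothness 8 px, `sigma_g = 0.05`, bleach 0.3% per slice,
speckle off. These magnitudes are package conventions chosen to be
plausible for paraffin-grade material — misalignment of a couple of pixels,
stretching around a pixel and a half, staining variation of a few per cent
— not estimates from any particular dataset. Every artifact class draws
from its own seeded stream derived from the root seed, so disabling one
class leaves the others' draws untouched and the recorded ground truth
(transforms, fields, gains, speckle coordinates) is exact.

What passing phantom tests does **not** show: the phantom has hard-edged,
noise-free geometry, no optical blur, no chromatic effects, no section
thickness averaging, and its elastic model is a smooth random field rather
than mechanical stretching. Results on real micrographs will be noisier in
every respect; the phantom establishes correctness of the machinery, not
field performance.

## Problem sizes and test design

The test suite builds all fixtures in code. Oracle comparisons run on 8³
volumes against brute-force (triple-loop) convolution and an independently
coded explicit diffusion scheme, both within ±1 gray level; the renderer is
checked against the closed-form over operator on two-sample rays.
Registration recovery uses 50 seeded trials on 64×64 smooth synthetic
slices (tolerance 0.25 px / 0.25°); end-to-end stack recovery uses
z-uniform phantoms of 10–40 slices (0.3 px / 0.3°); the full-pipeline and
striation demonstrations use the default 64×64×40 phantom. These sizes were
chosen so the whole suite runs in a few minutes on one core while still
exercising every code path at meaningful scale.

## Known limitations

- Alignment is rigid only; elastic distortion is reduced by 3D filtering,
  not corrected geometrically. External-marker congruencing approaches can
  do better when markers exist.
- Sequential propagation accumulates drift over very long series; there is
  no global adjustment.
- The edge-preserving filter is an interpretation of a proprietary
  algorithm's parameter set (see above).
- 16-bit and floating-point stacks, surface rendering, stereo pairs,
  perspective projection, and proprietary mesh formats are out of scope.
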