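---
title: "Aligning 4D micro-CT scans and quantifying plant organ torsion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning 4D micro-CT scans and quantifying plant organ torsion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlapse)
```

## The problem

A living plant scanned weekly in a micro-CT scanner yields one
reconstructed voxel volume per session. Between sessions the specimen is
taken out of the scanner and put back, so consecutive reconstructions
differ by a rigid repositioning of the whole container on top of the
biological changes of interest — root elongation, organ bending, and the
axial rotation (twisting, and past 180° *resupination*) that this package
exists to measure. Reconstructions can also differ in grid size when a
growing specimen forces taller scans. The pipeline therefore runs four
stages: **harmonize** (one common voxel grid), **register** (undo the
rigid repositioning), **bin + render** (turntable maximum-intensity
projections assembled into a time-lapse video), and **quantify**
(orientation and roll angle series turned into classified movement
events).

## Conventions

Volumes are indexed `(x, y, z)` with `z` the slice index counted
bottom-to-top; slice files sort in ascending z. All coordinates in
transform parameters are 0-based, rotations are Euler angles in degrees
applied about z, then y, then x, around the grid center `(dim − 1)/2`,
and translations are in voxels. The forward point map is
`T(p) = R(p − c) + c + t`; resampling computes `out(x) = vol(T⁻¹ x)` by
trilinear interpolation with zero fill outside the grid. In-plane angles
are measured from the image vertical, counterclockwise positive with y
up, so "clockwise" in a report means a negative angular change — this
makes event tables read like figure captions.

## Harmonization

Oversized scans are cropped to the per-axis minimum extent over the
sequence. Depth mismatches remove only the highest-index (top) slices:
the container base is the stable anatomical anchor and plants grow
upward, so the top of a taller reconstruction is the expendable part.
The acquisition protocol does not normally produce in-slice (x/y)
mismatches; when they occur the volume is center-cropped symmetrically,
which keeps the rotation axis near the grid center for registration, and
the deviation is logged. No padding mode exists — volumes are cropped,
never zero-padded — so harmonization never fabricates voxel values, and
retained voxels are bit-identical to the input (an exactness the tests
assert). Harmonization is idempotent. Missing `geometry.toml` metadata is
repaired with explicit defaults (1 mm voxels, zero rotation-axis offset)
and the repair is written back to the timepoint folder, so downstream
stages always find geometry on disk.

## Registration

Every timepoint is registered directly to the first scan (all-to-first),
not chained pairwise through resampled intermediates, which would
accumulate interpolation drift; only the search *initialization* chains
from the previous timepoint's result, since growth between adjacent weeks
is small. The metric is normalized cross-correlation. Three details of
the metric matter more than the optimizer and are worth recording:

- **Support.** The metric is evaluated over the inscribed cylinder of the
  grid, intersected with the in-bounds footprint of the resampled
  candidate. The cylinder is invariant under rotation about z, so rotated
  candidates are not penalized for the zero-filled corners resampling
  introduces; the footprint intersection removes the bias that appears
  when a large translation pushes content off the grid and zeros are
  compared against real structure.
- **Consistent smoothing.** Trilinear resampling low-pass filters each
  candidate by an amount that depends on its rotation and on the
  fractional part of its translation. On sharp data that inconsistency
  can outvote alignment: an unrotated candidate whose best shift is
  near-integer is evaluated nearly blur-free, and the dominant, almost
  rotationally symmetric container then prefers it regardless of the
  true rotation. The global search therefore runs on 3×3×3 box-smoothed
  copies of both volumes — once the data's intrinsic scale exceeds the
  interpolation blur, candidates compete on alignment alone — while the
  final local refinement and the reported score use the raw volumes.
- **Scalloping.** Interpolation imprints a one-voxel-period ripple on
  the metric. Off-lattice jittered sampling (below) removes most of it;
  per-axis integer-offset scans between stages guard against what
  remains.

The search itself: one global FFT cross-correlation at the
initialization provides the translation baseline; everything after that
is profile scans over the z rotation in which each angle candidate
receives a short quadratic translation polish warm-started from its
neighbour (rotation about the grid center and in-plane translation form
a shallow ridge that coordinate-wise refinement cannot climb). A coarse
5° scan over the full range — run in both directions, since the warm
start is path dependent across 5° jumps — and a 0.5° scan settle the
basin on the smoothed volumes; a 0.25° scan and a joint Nelder–Mead
pass on the raw volumes deliver sub-degree, sub-voxel precision. All of
these stages evaluate the NCC by trilinear sampling at a fixed, thinned
subset of the support whose points carry a deterministic
low-discrepancy jitter off the voxel lattice: on-lattice sampling gives
every point the same fractional phase, imprinting a one-voxel ripple
("scalloping") that splits the metric's peak into near-equal modes a
degree apart, and jittering the sample phases averages that ripple
away. Each evaluation costs milliseconds and the jitter is fixed, so
re-runs are bit-identical. Multi-resolution shortcuts were evaluated and
rejected: block-averaged volumes lose exactly the off-axis structure
(roots, leaves, marker) that makes the vertical-axis rotation
identifiable against the dominant, nearly cylindrical container.

Only the z rotation is searched globally. An upright specimen returned to
a scanner holder is repositioned mostly by rotation about the vertical
axis; out-of-plane tilts are small and are refined locally when the
initialization carries them (`refine_all`).

Binning ("factor 8" by default, one pass of non-overlapping block means,
not factor 2 applied eight times) happens *after* registration: its
purpose is rendering economy and noise reduction, and registering at full
resolution keeps sub-voxel accuracy available where it exists.

## Rendering

Turntable frames are maximum-intensity projections: deterministic,
parameter-free, and adequate for thin bright plant tissue against a dark
background, in contrast to transfer-function ray-casting, which would
make the output depend on opacity settings no one can reproduce later.
The default azimuth step is 10° (36 views per timepoint); frames are
numbered globally from 0 as `capture_00000.png` upward and each carries
its scan label burned in with a built-in 5×7 bitmap font, so the week of
any movement can be read directly off the video. Video assembly defaults
to 1 frame per 5 s. When an `ffmpeg` binary is on the PATH the frames are
encoded to H.264/yuv420p MP4; otherwise a built-in RIFF writer produces
an uncompressed RGB24 AVI with the same frame timing in its header
metadata. The PNG frames are the authoritative archival output either
way.

## Movement quantification

From 2D photographs taken on a copy stand, orientation is the angle of
the organ mask's principal axis (second central moments) from the image
vertical, in (−90°, 90°]; roll is the azimuth of a marked reference point
about the organ midline. Roll series are unwrapped by mapping successive
differences into (−180°, 180°] and summing — the *unwrapping hypothesis*
is that true rotation between weekly observations stays below 180°,
which weekly sampling of these slow movements supports; a double
resupination (360°) is therefore detectable only cumulatively across
timepoints, never from a single pair. Events are maximal monotone runs
per channel with total change at least 5°; runs in the orientation
channel are bending, runs in the roll channel are twisting below 180° and
resupination from 180° up (the boundary is closed at 180°: a 180° turn
*is* a resupination). The 5° default threshold balances protractor-scale
precision against observation noise; reported movements in this domain
are typically 15° and larger, so the default is deliberately permissive
and exposed as a parameter. Bending is measured in the fixed camera's
projection plane; no attempt is made to recover out-of-plane bending from
single photographs.

## The phantom

The synthetic generator is the ground-truth substrate for every test. It
emulates the scanned specimens: a cylindrical container (radius 24 of a
64³ grid) with a bright wall and base, a plant body, three leaves of
unequal size fanning out at unequal azimuths, and tubular roots
(distance-to-centerline fields with a one-voxel soft edge, so sub-voxel
motion is visible to registration) that elongate at the tip, tilt at a
bend rate, and carry a bright surface bead whose azimuth about the root
axis advances at the roll rate — 45°/timepoint by default, a weekly
cadence that completes a resupination in four intervals, matching the
week-scale resupination the imaging protocol was built to catch. The
whole specimen is rigidly repositioned between sessions (z rotation
within ±15°, translation within ±5 voxels by default) and Gaussian noise
(2% of dynamic range) is added last and clipped to the stored [0, 1]
detector range, as a proxy for reconstruction noise; Poisson projection
noise and X-ray physics are out of scope. The leaves are not decoration:
a specimen with a nearly cylindrical silhouette makes the vertical-axis
rotation unidentifiable, and real plants are exactly as asymmetric as
their leaves. Two construction rules keep the ground truth well-posed:
the helical wobble fades out smoothly around the marked arc position, so
the section carrying the bead is locally straight and the frame in which
the bead rotates is unambiguous (on a curved centerline the axis a
tracker fits and the frame a surface marker rotates in genuinely
disagree); and the leaves sit below the marked root sections, so no
other organ grows through the marker's neighbourhood and merges with the
tube. Generation is bit-exactly deterministic given the seed, with the
leading timepoint always unperturbed so it can serve as the reference
frame.

What the phantom does *not* emulate: new organs appearing between weeks,
intensity drift between sessions, bilaterally symmetric specimens that
genuinely confuse front and back, and deformable motion. Passing the
phantom suites therefore shows the pipeline recovers known rigid motion
and roll under realistic noise; it does not show robustness to organ
emergence or symmetric specimens, both of which degrade real-data
alignment.

## Problem sizes and numerical choices

The test suites run registration recovery on 40 seeded 64³ phantom pairs
(rotations within ±20°, translations within ±10 voxels, 5% noise; the
acceptance bar is 1° / 0.5 voxel in at least 95% of trials), an
end-to-end phantom-to-roll-rate loop over 10 seeded replicates of five
weekly timepoints at 2% noise (bar: mean per-step roll error under
2°/timepoint and resupination onset within one timepoint), and 1000
wrap/unwrap round-trip walks. The 64³ default grid keeps a full suite in
the tens of minutes on one core. Degenerate inputs are rejected loudly:
empty volumes cannot be registered (the metric is undefined), isotropic
masks have no orientation (principal-axis eigenvalue ratio below 1.05),
a marker on the midline has no azimuth, and a phantom whose roots cannot
fit its container is refused rather than silently clipped.

## Open interpretation choices

Two readings were fixed deliberately. "Binning eight times" is read as a
single factor-8 binning pass (not eight factor-2 passes, which would
collapse 256-fold); the factor is a parameter, so either reading is
available. And the fine-scan reference strategy is all-to-first rather
than consecutive-pair chaining, trading a slightly harder individual
search (larger cumulative motion per pair) for zero drift accumulation;
the chained initialization recovers most of the easier-search benefit.
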