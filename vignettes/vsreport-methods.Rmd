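---
title: "Measurement conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsreport)
```

This vignette records how `vsreport` defines its measurements, why the
defaults are what they are, and where the design was genuinely open. It is
the companion to the reference documentation: the function pages say *what*
each operation returns; this document says *why* it is defined that way.

## The measurement model

Vestibular schwannoma surveillance compares tumour size across years of
MRI. The package operates purely on segmentation label volumes — label 1
for the intrameatal compartment (inside the internal auditory canal), label
2 for the extrameatal compartment — and never touches image intensities.
That choice makes every quantity a deterministic function of the mask and
its voxel geometry.

**Canonical frame.** Every volume is reoriented to RAS on load, so the
third array axis is inferior–superior and an "axial slice" is always a
section across it. Diameters are measured in-plane per axial slice, not as
3D oblique ferets: axial in-plane measurement is how the clinical
measurement is defined and read on a workstation, and it keeps the result
comparable to a radiologist's caliper reading. Anisotropic voxels are
supported throughout and volumes are never resampled — resampling would
silently change both volumes and diameters.

**Pixel-centre convention.** All distances, extents and projections use
pixel-centre coordinates: pixel $(i, j)$ sits at $((i-1)s_x, (j-1)s_y)$ mm.
A two-pixel mask at grid offset (3, 4) with unit spacing therefore has
diameter exactly 5 mm, and a 6-pixel row spans 5 mm, not 6. The convention
is unambiguous and oracle-checkable; users comparing against caliper-style
readings (which land on region boundaries, not centres) should expect
differences up to one pixel.

**Diameters.** The maximum in-plane diameter of a region is the maximum
Euclidean distance between any two of its pixel centres, computed as convex
hull plus rotating calipers. The implementation prunes collinear hull
vertices before the antipodal sweep and checks every vertex the sweep
passes during a parallel-edge tie; the test suite holds it to *exact*
equality with an $O(n^2)$ brute force over thousands of random masks.
Tie-breaks: the slice achieving the maximum is the smallest slice index.

**Volumes.** Compartment volumes are voxel counts times the voxel volume,
reported in cm³. $V_{whole} = V_{intra} + V_{extra}$ holds exactly because
the labels partition the mask.

**Meatal axis.** The diameter-selection rules need directions "parallel"
and "perpendicular" to the porus. No published operational definition
exists, so the package isolates the choice in one operation: interface
voxels are extrameatal voxels 6-adjacent to an intrameatal voxel; their
in-plane coordinates, pooled over all axial slices, are fit by the dominant
eigenvector of their 2×2 covariance. That direction — the in-plane trace of
the porus plane — is $u_\parallel$; the canal direction is $u_\perp$. The
axis is undefined with fewer than two interface voxels or when the
covariance is isotropic within $10^{-9}$ (e.g. a point-like interface); all
downstream consumers treat "undefined" as a first-class answer and fall
back to the whole-tumour diameter. This is the largest modelling gap in the
package and deliberately swappable.

**Directional extents.** Extents are ranges (max − min) of pixel-centre
projections onto $u_\parallel$ / $u_\perp$, measured on the reference slice
(the slice of the whole-tumour maximum diameter). A compartment absent on
the reference slice but present elsewhere is measured on the slice with the
most interface voxels instead; a compartment absent everywhere contributes
zero.

**Component cleaning.** Before measurement the largest 26-connected
component of the tumour mask is kept (26-connectivity for components,
6-adjacency for interface detection). Components below `minVoxels`
(default 5, about 0.6 µL at 0.5 mm isotropic) are discarded outright —
below that size a "component" is segmentation noise, not tumour. Exact size
ties go to the component with the lexicographically smallest centroid, so
cleaning is deterministic.

## Growth classification

The significant-growth criteria are the EAONO ones: diameter increase
> 2 mm, whole-tumour volume change > 1.2 cm³, or volume change > 20%. All
three are strict inequalities — a change of exactly 2.0 mm is not growth —
and the volume criteria always use the *whole-tumour* volume, which is also
the quantity treatment planning uses.

**Equivocal band.** Clinical reporting uses an equivocal category between
"no change" and "growth", but no numeric definition is published. The
package defines it as: any change whose magnitude exceeds
`equivocalFraction` × threshold (default 0.5) without any criterion firing.
The fraction is a visible, configurable parameter of `vsThresholds()`
rather than a buried constant, precisely because it is a convention, not a
finding.

**Diameter comparability.** When the displayed diameter type differs
between two compared sessions (DEM at baseline, DWT at follow-up, say),
serial values are not comparable; the delta is then computed on DWT for
both sessions and the assessment carries a `basisSwitched` flag that the
report surfaces as a note. Reduction is colour-coded green, like no growth:
the report vocabulary has exactly three colours.

**Asymmetry of the percentage criterion.** Percentage change is relative to
each comparison's own baseline, so growth of $+x\%$ mirrors to
$-x/(1+x)\%$: a volume ratio in $(1.20, 1.25]$ is growth in the forward
direction but its reverse is not, by itself, a reduction. This is a
property of relative thresholds, not a bug; the symmetry tests cover
coherent scalings outside that sliver.

## The phantom

The phantom emulates the anatomy the measurements assume: an intrameatal
cylinder (length 10 mm, radius 3 mm by default — a canal-filling portion)
along a canal direction at 30° in-plane, cut flat at the porus plane and
joined there to an extrameatal half-ellipsoid (semi-axes 9 × 6 × 5 mm, a
moderate tumour), voxelized at 0.5 mm isotropic — a typical high-resolution
surveillance acquisition. The flat porus cut is intentional: it produces a
disc-shaped intra/extrameatal interface with enough voxels for a stable
principal-direction fit, while keeping every ground-truth quantity in
closed form (cylinder $\pi r^2 L$; half-ellipsoid $\tfrac{2}{3}\pi abc$).
Truth diameters come from densely sampled boundary points of the continuous
central cross-section (0.25° arc steps), which is independent of the voxel
pipeline. Longitudinal series scale every linear dimension by a per-session
factor, so truth volumes scale with the cube.

Optional surface jitter — a seeded sum of six random cosine waves
perturbing the implicit surfaces — emulates segmentation-boundary
variability for robustness tests; ground truth is exact only at zero
jitter. All randomness flows from the single `seed` parameter, and the
generator restores the caller's RNG state.

What the phantom does *not* emulate: MR intensities, segmentation failure
modes (over-/under-segmentation, missed tumours), irregular or cystic
tumour shapes, and inter-scan repositioning. Passing the phantom-recovery
tests therefore demonstrates that the geometry pipeline is correct on
well-formed two-compartment masks — it says nothing about segmentation
quality on real images, which remains the upstream model's responsibility.

## Numerical choices and degenerate inputs

- Voxel values within $10^{-6}$ of an integer are rounded on load; anything
  else, or any label outside {0, 1, 2} after optional remapping, is an
  error. NIfTI stores spacing as float32, so spacing is snapped to
  micrometre precision on read to make write/read round-trips exact.
- Empty masks flow through the whole pipeline: diameter 0 with undefined
  endpoints, volumes 0, "entirely intrameatal" true, growth percentages
  undefined (and never triggering) at zero baseline volume.
- Dates convert to months through the mean month length (30.44 days),
  matching the report's continuous months axis.
- Phantom-recovery tolerances follow discretization, not tuning: one voxel
  diagonal for diameters (the worst case for a boundary-cell centre), 5%
  for volumes at radii ≥ 10× spacing (surface-cell counting error), 5° for
  the axis direction.

## Reports and determinism

HTML is the canonical output: panels and charts are emitted as inline SVG
by small deterministic writers (fixed decimal formatting, no timestamps),
so rendering the same spec twice is byte-identical and golden-file tests
are meaningful. The style (palette, geometry, CSS) is versioned; changing
it means bumping `styleVersion`. The PDF flavour is drawn with base R
graphics for convenience and is *not* byte-stable, because the PDF format
embeds creation timestamps. STL meshes are exact voxel surfaces: closed by
construction, with enclosed volume equal to the voxel-count volume.

One published detail is implemented as its inverse: the suppression rule
for volume display reads, literally, that volumes are not presented when
the tumour spans *more* than one axial slice, which contradicts the
published example reports showing volumes for large multi-slice tumours.
The package suppresses volumes when the tumour occupies ≤ 1 axial slice —
single-slice volumes are unreliable — and exposes the toggle
(`suppressSingleSlice`) so either reading is available.

## Problem sizes in the test suite

The suite exercises phantoms at 0.4–1 mm spacing (arrays up to roughly
120 × 100 × 40), 220+ random masks for the calipers/brute-force
equivalence, the full 16³ grid of directional extents for the selection
rules, and full pipeline runs on two- and three-session timelines; it
completes in well under a minute. These sizes were chosen to make every
oracle exact at interactive runtimes; nothing in the implementation is
specific to them, and clinical-resolution volumes simply take
proportionally longer.

## Known limitations

- The meatal-axis definition is this package's own operationalization; on
  highly irregular interfaces the principal direction may not match what a
  radiologist would call the porus orientation (the post-treatment
  boundary-irregularity problem is documented clinical experience).
- D<sub>EM</sub> is the unconstrained in-plane maximum of the extrameatal
  region; consensus-style readings measured parallel to the petrous ridge
  can differ. The directional extents are used only inside the selection
  algorithm.
- Sessions are measured independently; no registration means slice-level
  quantities (reference slice index) are not comparable across sessions,
  only the derived scalars are.
- Growth assessment is purely criteria-based; it does not model growth
  rate, Koos grade, or any clinical covariate.
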