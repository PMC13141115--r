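---
title: "Preparing sequential multiplex immunofluorescence images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing sequential multiplex immunofluorescence images}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifprep)
```

## The problem

Sequential (cyclic) multiplex immunofluorescence re-stains one specimen —
an FFPE tissue section, a primary-cell culture, or cells on a porous
membrane chip — through many stain–image–strip cycles. Every cycle yields
a tile scan per channel: a nuclear (DAPI/Hoechst) reference plus marker
channels, sometimes a dedicated autofluorescence channel, and for chips a
z-stack per tile. Before any per-cell analysis is meaningful, these raw
tiles must be corrected for illumination, assembled into mosaics, cleaned
of diffuse background, aligned across cycles, and fused into one
registered multichannel hyperstack. `mifprep` implements that preparation
chain plus the downstream imaging-cytometry step: segment nuclei, measure
per-cell marker overlap, and assign identities by the ≥ 60 % nuclear-
overlap rule.

All rasters are unsigned 16-bit, indexed (row, col) with a top-left
origin; offsets are 0-based. After every division or scaling step the
result is rounded half-up and clipped to [0, 65535] before anything else
happens, so no stage can leak fractional or out-of-range intensities into
the next.

## Stage models and the parameters that matter

### Flat-field (shading) correction

Vignetting is modelled as multiplicative: `observed = truth × field`,
with `field` smooth and tile-frame-fixed. `build_shading_field()` turns a
shading-reference image (uniform fluorescent target) into the correction
field: intensities are floored at the `floor_quantile` quantile (default
0.01) so dead or dark pixels cannot explode the division — if that
quantile is itself zero the floor falls back to the smallest positive
reference value — and the floored image is normalized to mean 1.
`correct_shading()` divides by the field; on synthetic `truth × field`
data the truth is recovered to within one grey level. No dark-frame term
is included because the model is purely multiplicative.

### Brightfield flattening

Brightfield snapshots get a different treatment (division by a Gaussian-
smoothed copy of the image itself, rescaled by the global mean), because
no shading reference exists for transmitted light. `sigma_px` (default
50) must sit far above the texture scale and below the illumination-
gradient scale; smoothing uses reflective boundaries. The global mean is
preserved to well under 1 % on unclipped images.

### Weighted z-projection

Chip acquisitions arrive as focal series because cells sit on a curved
membrane. `project_weighted()` collapses a stack by a per-pixel weighted
average with weights `ε + local 3×3 variance` (ε = 1e-6 guards the
all-flat case), normalized per pixel, so in-focus slices dominate;
`mode = "mean"` is the plain average. The exact weighting of the vendor
projection is not documented anywhere we could follow, so both modes are
labelled approximations; the contrast weighting matches the purpose
(structure at varying focus) and demonstrably tracks the sharp member of
a sharp/defocused pair more closely than the plain mean.

### Stitching

Nominal tile origins come from the grid geometry: tile (r, c) sits at
`(r·H·(1−ov), c·W·(1−ov))`. Real stages jitter by a few pixels, so
placements are refined pairwise on the nominal overlap strips. We
deliberately do **not** use whitened phase correlation here: on strips a
few dozen pixels wide the cross-power spectrum is dominated by truncation
edges, and in our experiments it returned near-zero offsets for true
jitters of a few pixels. Instead each adjacent pair is scored by
exhaustive normalized cross-correlation over the jitter search window
(± (overlap − 2) px, so at least two pixels of common strip always
remain), refined to subpixel precision by a parabolic fit quantized to
`1/upsample` px (default 1/10). Correlation-weighted placements are
accumulated from the top-left anchor tile along the maximum-correlation
spanning tree; any pair scoring below `min_correlation` (default 0.3)
falls back to its nominal offset and is flagged in the pair table.
Blending feathers overlaps linearly with weights proportional to the
distance to each tile's nearest edge; single-coverage pixels are
bit-exact copies, and uncovered canvas is zero and reported in the
mosaic's `coverage` attribute.

### Rolling-ball background

The diffuse background is the grayscale opening of the image with a
non-flat ball element `z(x,y) = sqrt(r² − x² − y²)`: erosion then
dilation, computed in compiled code with out-of-domain offsets ignored,
which keeps the opening anti-extensive (`background ≤ image`) for the
symmetric ball. The radius (default 50 px, always logged) must exceed the
largest genuine foreground object. Above radius 16 the default mode
follows the classical shrink–roll–expand strategy: block-minimum
downscale by `ceiling(r/16)`, roll at the reduced radius, bilinear
expansion, clip under the image. Exact mode is always available and is
held bit-equal to a brute-force oracle in the tests.

### Autofluorescence subtraction

Tissue and debris autofluorescence recorded as its own channel is removed
from configured marker channels by `marker − scale·af`, floored at zero.
`scale = "auto"` estimates the leak as the least-squares slope of marker
on autofluorescence restricted to pixels below the marker's median —
signal-poor pixels, so genuine staining does not bias the slope — clipped
to [0, 3].

### Cross-cycle registration and retention QC

Remounting and re-imaging the same section drifts predominantly
translationally, so registration is translation-only (rotation/affine is
a declared non-goal). Each cycle's nuclear plane is aligned to the
reference cycle (default the first) by phase correlation — here the
overlap is essentially complete, which is exactly the regime where
whitened phase correlation excels — with subpixel refinement by an
upsampled matrix-multiply DFT evaluated on a ±1.5 px neighbourhood of the
integer peak (default 1/10 px). Every plane of a cycle receives exactly
its cycle's nuclear transform, preserving within-cycle co-registration.
Estimated shifts beyond `max_shift_frac` (default 10 % of the frame) are
treated as failures: the cycle keeps its position and is flagged rather
than silently mangled.

Tissue retention is quantified per cycle on Otsu-binarized nuclear masks:
Dice `2|A∩B|/(|A|+|B|)` against the reference cycle plus the Pearson
correlation of raw intensities over the union support. The flagging
threshold (Dice 0.7) is a reporting default, never an enforcement; with a
fraction `l` of nuclear area lost the expected Dice is `2(1−l)/(2−l)`,
which the QC reproduces on synthetic loss.

### Segmentation and the overlap rule

`segment_nuclei()` is a classical chain: Gaussian smoothing (σ = 1.5 px),
Otsu threshold, hole filling, then watershed on the distance transform to
split touching nuclei. The seed-suppression radius is
`ceiling(sqrt(min_area)/2)` — two maxima separated by at least the
diameter of the smallest admissible nucleus both survive — and
`seed_tolerance` (default 0.5 distance-map units) controls shallow-peak
merging. Components outside [`min_area`, `max_area`] (defaults 30 and
2000 px²) are discarded. Label maps from external segmenters (e.g.
deep-learning tools) can be imported from integer TIFF instead;
segmentation here is intentionally classical, not a re-implementation of
any published network.

Marker channels are binarized by Otsu (or per-channel fixed thresholds —
membrane and cytoplasmic markers vary too widely for one rule), and each
cell's overlap fraction is the share of its nuclear pixels inside the
mask. A marker qualifies at fraction ≥ 0.60. Several qualifying markers
are resolved by argmax under `exclusive = TRUE`, but a near-tie (top two
within 0.01) is reported and left unassigned rather than guessed: adjacent
cell types share membrane signal in projection, and inventing
biphenotypic cells is the failure mode this rule exists to prevent.
Intensities of markers incompatible with the assigned identity are kept
in the table but flagged invalid — recorded, not deleted.

## What the synthetic generator emulates

`make_scene()` freezes, under one master seed, everything the pipeline
must undo: non-overlapping nuclei (radii 4–6 px) with multinomial class
memberships; a per-channel vignette (25 % corner attenuation); per-cycle
integer stage drift (≤ ±8 px) and per-tile jitter (≤ ±3 px); per-cycle
signal retention `0.95^(cycle−1)`, standing in for antibody-functionality
loss across stripping cycles (a modelling choice, not a measured value);
a broad Gaussian haze (amplitude 800); autofluorescent debris blobs that
leak at 30 % into marker channels; Poisson shot noise plus Gaussian read
noise (σ = 2); and, in chip mode, a lattice of small round membrane
pores. Membrane markers are rendered over the member cell's 3 px-dilated
footprint with a brighter rim — a strict annulus disjoint from the
nucleus would make the nuclear-overlap rule vacuous, and 2-D projections
of membrane staining do cover the nucleus. The default study conditions
are 400 cells, two classes at 50/50, six cycles, a 2×2 grid of 232×232 px
tiles at 10 % overlap (a 441×441 px frame).

What it does **not** emulate: realistic optics (no PSF), histology
texture, chromatic shifts, rotation or nonrigid deformation, stripping
artefacts beyond a global retention factor, and 3-D geometry. Passing
tests therefore demonstrate algorithmic correctness under the declared
noise model, not performance on real tissue.

## Numerical choices

* Rounding is half-up (`floor(x + 0.5)`), applied after every division,
  before the clip to [0, 65535].
* Gaussian smoothing uses edge-inclusive mirror padding; kernel radius
  `3σ`, capped below the image extent.
* Phase-correlation spectra are normalized with a 1e-12 magnitude floor;
  correlation scores are Pearson over the aligned overlap, clamped to
  [0, 1], and 0 for degenerate (constant) regions.
* Stitching tie-breaks: `which.max` takes the first (smallest-shift)
  candidate on the search grid; the parabolic offset is confined to
  ±0.5 px.
* Degenerate inputs error early and explicitly: constant planes for
  Otsu/registration, all-zero shading references and brightfield images,
  empty z-stacks, unregistered stacks passed to QC or quantification.
* Problem sizes in tests and the acceptance script (chosen to exercise
  every path at comfortable desk-scale): 32×32 oracle planes, 256×256
  registration frames, a 3×3/160 px stitching mosaic, and the default
  441×441 six-cycle fixture for the end-to-end runs.

## Known limitations

Translation-only registration will under-serve sections that rotate
between cycles; the QC report (Dice per cycle) is the intended detector
for that failure. The classical segmenter undercounts dense nuclear
clusters relative to trained models — the import path exists precisely so
external label maps can be slotted in. Autofluorescence handling is a
single-channel scaled subtraction, not spectral unmixing. The stitcher
assumes a regular grid with known overlap and traversal order; both are
required configuration, since exported tiles carry no stage metadata.
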