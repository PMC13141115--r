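# mifprep

Image preparation and imaging cytometry for **sequential multiplex
immunofluorescence (mIF)** microscopy.

Cyclic mIF images one specimen — an FFPE tissue section, a primary-cell
culture, or cells on a porous membrane chip — through repeated
stain–image–strip cycles. Every cycle produces overlapping tile scans per
channel: a nuclear (DAPI) reference plus marker channels, optionally a
dedicated autofluorescence channel. Raw tiles are unusable for
quantification until they have been corrected, assembled and aligned.
`mifprep` is that preparation chain, written for image analysts who
receive exported TIFF tiles and need a registered multichannel hyperstack
and a per-cell table out the other end:

1. **Shading correction** — divide each tile by a normalized flat-field
   built from a shading-reference image (`build_shading_field()`,
   `correct_shading()`); brightfield snapshots are flattened by Gaussian
   division instead (`brightfield_flatten()`).
2. **Stitching** — refine nominal grid placements on the tile-overlap
   strips, solve global positions along a maximum-correlation spanning
   tree, blend with linear feathering (`refine_offsets()`,
   `blend_mosaic()`).
3. **Rolling-ball background subtraction** — grayscale opening with a
   non-flat ball element, `background(x) ≤ image(x)` everywhere
   (`subtract_background()`).
4. **Hyperstack assembly** — per-cycle stacks concatenated cycle-major
   into one container with a channel manifest
   (`assemble_hyperstack()`, `write_hyperstack()`).
5. **DAPI-referenced registration** — per-cycle translation estimated on
   the nuclear channel by subpixel phase correlation and applied to every
   channel of that cycle (`register_cycles()`); cross-cycle tissue
   retention QC by Dice/Pearson on binarized nuclear masks
   (`dapi_retention_qc()`).
6. **Autofluorescence subtraction** — `marker − scale·af` with an
   auto-estimated leak coefficient (`subtract_autofluorescence()`).
7. **Imaging cytometry** — nucleus segmentation (Otsu + watershed, or an
   imported label map), per-cell marker overlap fractions, and identity
   assignment by the rule that a cell carries a marker only when its
   *nucleus* is at least 60 % covered by the binarized marker mask:

   identity(c) = argmax_m { f_m(c) : f_m(c) ≥ 0.60 },  f_m(c) = |c ∩ M_m| / |c|

   with near-ties reported and left unassigned rather than guessed
   (`segment_nuclei()`, `overlap_fractions()`, `assign_identity()`,
   `quantify()`).

Chip acquisitions (z-stacks over a porous membrane) are first collapsed
by a contrast-weighted orthogonal projection (`project_weighted()`).

A seeded synthetic-acquisition generator (`make_scene()`,
`simulate_acquisition()`) produces ground-truthed multi-cycle fixtures —
known shading fields, stage jitter, inter-cycle drift, signal decay,
haze, debris, chip pores — so the whole pipeline is testable without any
real data.

## Worked example

Simulate the default six-cycle, 400-cell, two-class acquisition and run
the full pipeline on it:

```r
library(mifprep)

fx <- file.path(tempdir(), "fixture")
sim <- simulate_acquisition(n_cells = 400, cycles = 6, seed = 17,
                            out_dir = fx)
res <- run_pipeline(list(
  input_dir = fx, manifest = "manifest.csv",
  output_dir = file.path(tempdir(), "run"),
  grid = list(rows = 2, cols = 2, overlap_fraction = 0.1,
              acquisition_order = "row_major", tile_shape = c(232, 232)),
  autofluorescence = list(enabled = TRUE,
                          channels = list("LYVE-1", "IBA1"))))

res$hyperstack
#> <HyperStack 9 planes (6 cycles) of 442 x 441, registered>

res$qc
#>   cycle  dice pearson flagged
#> 1     1 1.000   1.000   FALSE
#> 2     2 0.996   0.998   FALSE
#> 3     3 0.995   0.998   FALSE
#> 4     4 0.996   0.998   FALSE
#> 5     5 0.996   0.998   FALSE
#> 6     6 0.995   0.998   FALSE

head(res$cell_table[, c("cell_id", "area_px", "frac_LYVE-1", "frac_IBA1",
                        "assigned_identity")], 5)
#>   cell_id area_px frac_LYVE-1 frac_IBA1 assigned_identity
#> 1       1     146           1  0.041096            LYVE-1
#> 2       2     137           0  1.000000              IBA1
#> 3       3     135           1  0.051852            LYVE-1
#> 4       4     137           1  0.000000            LYVE-1
#> 5       5     138           1  0.007246            LYVE-1

table(res$cell_table$assigned_identity)
#>   IBA1 LYVE-1
#>    206    192
```

Reading the output: the six nuclear planes stay registered to Dice
≥ 0.995 across all cycles (no flagged tissue loss); each detected cell
carries its overlap fraction per marker, and identities follow the 60 %
nuclear-overlap rule — e.g. cell 1's nucleus is fully inside the LYVE-1
mask but only 4 % inside the IBA1 mask, so it is called LYVE-1⁺. Against
the generator's ground truth this run assigns > 99 % of cells their true
class.

A thin CLI wraps the same functions
(`exec/mifprep simulate|run|validate|qc`); outputs per run are
`hyperstack.tif` (+ JSON sidecar), `qc.json`, `cell_table.csv`,
`provenance.json` and a JSON-lines log.

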