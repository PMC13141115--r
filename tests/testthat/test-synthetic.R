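test_that("scene generation is seeded, proportion-faithful, and packing-aware", {
  empty <- make_scene(n_cells = 0, cycles = 2, seed = 1)
  expect_equal(nrow(empty$cells), 0)

  a <- make_scene(n_cells = 150, cycles = 3, seed = 77)
  b <- make_scene(n_cells = 150, cycles = 3, seed = 77)
  expect_identical(a$cells, b$cells)
  expect_identical(a$drifts, b$drifts)
  expect_identical(a$jitters, b$jitters)

  big <- make_scene(n_cells = 400, seed = 5)
  nA <- sum(big$cells$class == names(big$classes)[1])
  # 99 % binomial interval around 200 of 400 at p = 0.5
  expect_gte(nA, qbinom(0.005, 400, 0.5))
  expect_lte(nA, qbinom(0.995, 400, 0.5))

  # nuclei never overlap
  d <- as.matrix(dist(big$cells[, c("row", "col")]))
  diag(d) <- Inf
  rsum <- outer(big$cells$radius, big$cells$radius, `+`)
  expect_true(all(d > rsum))

  expect_error(make_scene(n_cells = 4000, seed = 1), "infeasible packing")
  expect_error(make_scene(classes = c(A = 0.7, B = 0.7)), "sum to 1")
})

test_that("noiseless renders repeat across cycles and close the loop with registration", {
  tr <- make_scene(n_cells = 80, cycles = 3, seed = 21, drift_max = 0,
                   retention_base = 1, jitter_max = 0)
  man <- scene_manifest(tr, autofluorescence = FALSE)
  r1 <- render_cycle(tr, 1, man[man$cycle == 1, ], noise = FALSE)
  r3 <- render_cycle(tr, 3, man[man$cycle == 3, ], noise = FALSE)
  expect_identical(r1[[1]]$tiles[[1]]$pixels, r3[[1]]$tiles[[1]]$pixels)

  # injected drift is recovered by shift estimation on the rendered frames
  trd <- make_scene(n_cells = 120, cycles = 2, seed = 8, jitter_max = 0,
                    grid = tile_grid(1, 1, 0.1, tile_shape = c(260, 260)))
  trd$drifts[2, ] <- c(5, -2)
  mand <- scene_manifest(trd, autofluorescence = FALSE)
  c1 <- render_cycle(trd, 1, mand[mand$cycle == 1, ])
  c2 <- render_cycle(trd, 2, mand[mand$cycle == 2, ])
  s <- estimate_shift(c1[[1]]$tiles[[1]], c2[[1]]$tiles[[1]])
  expect_lte(abs(s$dy - 5), 0.5)
  expect_lte(abs(s$dx - (-2)), 0.5)
})

test_that("shading correction of rendered tiles recovers the clean render within noise", {
  tr <- make_scene(n_cells = 60, cycles = 1, seed = 31, jitter_max = 0,
                   drift_max = 0, shading_strength = 0.35,
                   grid = tile_grid(1, 1, 0.1, tile_shape = c(200, 200)))
  man <- scene_manifest(tr, autofluorescence = FALSE)
  rec <- man[man$cycle == 1, ][1, , drop = FALSE]
  shaded <- render_cycle(tr, 1, rec, noise = TRUE)[[1]]
  clean <- render_cycle(tr, 1, rec, noise = FALSE)[[1]]
  field <- structure(list(field = mifprep:::scene_shading_field(tr, 1),
                          source = "reference_image"),
                     class = "ShadingField")
  corrected <- correct_shading(shaded$tiles[[1]], field)
  resid <- corrected$pixels - clean$tiles[[1]]$pixels / field$field
  # Poisson + read noise on amplitudes <= ~13000, inflated by the vignette
  # division; 6 sd of the worst-case pixel noise bounds the residual
  expect_lt(max(abs(resid)), 6 * sqrt(13000) / min(field$field))
  expect_lt(abs(mean(resid)), 3)
})

test_that("written fixtures contain every plane plus faithful truth tables", {
  dir <- withr::local_tempdir()
  sim <- simulate_acquisition(n_cells = 30, cycles = 2, seed = 13,
                              grid = tile_grid(2, 1, 0.12, tile_shape = c(120, 120)),
                              out_dir = dir)
  tiles <- list.files(file.path(dir, "tiles"))
  expect_length(tiles, nrow(sim$manifest) * 2)   # 2 tiles per channel
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), nrow(sim$manifest))
  truth <- read.csv(file.path(dir, "truth_cells.csv"))
  expect_equal(nrow(truth), 30)
  p <- read_plane(file.path(dir, "tiles", tiles[1]))
  expect_equal(dim(p), c(120L, 120L))

  # chip preset adds the pore lattice everywhere
  chip <- simulate_acquisition("chip", n_cells = 10, cycles = 1, seed = 2,
                               grid = tile_grid(1, 1, 0.1,
                                                tile_shape = c(120, 120)))
  af_free <- render_frame(chip$truth, "nuclear")
  no_pores <- chip$truth; no_pores$pores <- NULL
  expect_gt(sum(af_free), sum(render_frame(no_pores, "nuclear")))
})
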