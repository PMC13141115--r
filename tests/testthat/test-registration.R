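test_that("shift estimation recovers identity, integer, and subpixel translations", {
  sc <- textured_frame(n_cells = 150, seed = 3)
  ref <- mifprep:::clip_u16(sc$pixels)

  s0 <- estimate_shift(ref, ref)
  expect_equal(c(s0$dy, s0$dx), c(0, 0))
  expect_gte(s0$peak_correlation, 0.999)

  mov <- mifprep:::clip_u16(mifprep:::translate_pixels(ref, -7, 4))
  s1 <- estimate_shift(ref, mov, upsample = 10)
  expect_lte(abs(s1$dy - 7), 0.5)
  expect_lte(abs(s1$dx - (-4)), 0.5)

  movs <- mifprep:::clip_u16(mifprep:::translate_pixels(ref, -2.5, 0))
  s2 <- estimate_shift(ref, movs, upsample = 10)
  expect_gte(s2$dy, 2.3); expect_lte(s2$dy, 2.7)
  expect_lte(abs(s2$dx), 0.2)

  expect_error(estimate_shift(matrix(5, 32, 32), ref[1:32, 1:32]),
               "constant")
  sflag <- estimate_shift(ref, mifprep:::clip_u16(
    mifprep:::translate_pixels(ref, -40, 0)), max_shift = 10)
  expect_true(sflag$flagged)
  expect_equal(c(sflag$dy, sflag$dx), c(0, 0))
})

test_that("apply_shift composes with its inverse and closes the estimation loop", {
  sc <- textured_frame(n_cells = 100, seed = 12)
  ref <- image_plane(mifprep:::clip_u16(sc$pixels))
  expect_identical(apply_shift(ref, c(0, 0))$pixels, ref$pixels)

  fwd <- apply_shift(ref, c(3, 0))
  back <- apply_shift(fwd, c(-3, 0))
  H <- nrow(ref$pixels)
  expect_identical(back$pixels[4:(H - 3), ], ref$pixels[4:(H - 3), ])

  mov <- image_plane(mifprep:::clip_u16(
    mifprep:::translate_pixels(ref$pixels, -5, 3)))
  est <- estimate_shift(ref, mov)
  aligned <- apply_shift(mov, est)
  resid <- estimate_shift(ref, aligned)
  expect_lt(sqrt(resid$dy^2 + resid$dx^2), 0.5)
})

# Build a registered-ready hyperstack with known per-cycle drifts.
drifted_stack <- function(drifts, seed = 20) {
  sc <- textured_frame(n_cells = 130, seed = seed)
  nuc <- mifprep:::clip_u16(sc$pixels)
  mk <- mifprep:::clip_u16(render_frame(sc$truth, "marker",
                                        marker = names(sc$truth$classes)[1]))
  rows <- list(); per_cycle <- list()
  for (k in seq_len(nrow(drifts))) {
    rows[[k]] <- data.frame(
      cycle = rep(k, 2), channel_name = c("DAPI", "A647"),
      marker = c("DAPI", "MK"), fluorophore = c("DAPI", "A647"),
      exposure_ms = c(30, 200), role = c("nuclear", "marker"))
    shift_k <- function(m) mifprep:::clip_u16(
      mifprep:::translate_pixels(m, -drifts[k, 1], -drifts[k, 2]))
    per_cycle[[k]] <- list(cycle = k, planes = list(
      image_plane(shift_k(nuc)), image_plane(shift_k(mk))))
  }
  assemble_hyperstack(per_cycle, validate_manifest(do.call(rbind, rows)))
}

test_that("cycle registration recovers injected drifts and co-shifts all channels", {
  drifts <- rbind(c(0, 0), c(5, -2), c(-3, 8))
  hs <- drifted_stack(drifts)
  reg <- register_cycles(hs)
  expect_true(reg$stack$registered)
  expect_length(reg$shifts, 2)
  for (s in reg$shifts) {
    expect_lte(abs(s$dy - drifts[s$cycle, 1]), 0.5)
    expect_lte(abs(s$dx - drifts[s$cycle, 2]), 0.5)
  }
  # marker planes must receive exactly their cycle's nuclear transform:
  # after registration marker_k aligns with marker_1 to within 0.5 px
  m1 <- reg$stack$planes[[2]]
  for (cy in 2:3) {
    mk <- reg$stack$planes[[2 * cy]]
    resid <- estimate_shift(m1, mk)
    expect_lt(sqrt(resid$dy^2 + resid$dx^2), 0.5)
  }
  # post-condition: nuclear planes now coincide
  for (cy in 2:3) {
    nk <- reg$stack$planes[[2 * cy - 1]]
    resid <- estimate_shift(reg$stack$planes[[1]], nk)
    expect_lt(sqrt(resid$dy^2 + resid$dx^2), 0.5)
  }

  single <- drifted_stack(rbind(c(0, 0)))
  reg1 <- register_cycles(single)
  expect_length(reg1$shifts, 0)
  expect_identical(reg1$stack$planes[[1]]$pixels, single$planes[[1]]$pixels)
})

# Nuclear stack where cycle 2 has a fraction of nuclei erased (tissue loss).
loss_stack <- function(loss_area_fraction, seed = 33, n_cells = 250) {
  tr <- make_scene(n_cells = n_cells, cycles = 1, seed = seed,
                   radius_range = c(5, 5))
  full <- mifprep:::clip_u16(render_frame(tr, "nuclear"))
  n_drop <- round(loss_area_fraction * n_cells)
  keep <- tr$cells[seq_len(n_cells) > n_drop, , drop = FALSE]
  tr2 <- tr; tr2$cells <- keep
  lost <- mifprep:::clip_u16(render_frame(tr2, "nuclear"))
  rows <- data.frame(cycle = 1:2, channel_name = "DAPI", marker = "DAPI",
                     fluorophore = "DAPI", exposure_ms = 30,
                     role = "nuclear")
  hs <- assemble_hyperstack(list(list(cycle = 1, planes = list(image_plane(full))),
                                 list(cycle = 2, planes = list(image_plane(lost)))),
                            validate_manifest(rows))
  hs$registered <- TRUE
  hs
}

test_that("retention QC reports exact self-agreement and the analytic Dice under loss", {
  hs0 <- loss_stack(0)
  qc0 <- dapi_retention_qc(hs0)
  expect_equal(qc0$dice, c(1, 1), tolerance = 1e-9)
  expect_equal(qc0$pearson, c(1, 1), tolerance = 1e-9)
  expect_false(any(qc0$flagged))

  qc20 <- dapi_retention_qc(loss_stack(0.20))
  expect_lt(abs(qc20$dice[2] - 2 * 0.8 / 1.8), 0.03)

  # Dice decreases monotonically with increasing tissue loss
  dice <- vapply(c(0, 0.10, 0.20, 0.40),
                 function(l) dapi_retention_qc(loss_stack(l))$dice[2],
                 numeric(1))
  expect_true(all(diff(dice) < 0))

  blank <- loss_stack(0)
  blank$planes[[2]] <- image_plane(matrix(0, nrow(blank$planes[[1]]$pixels),
                                          ncol(blank$planes[[1]]$pixels)))
  qcb <- dapi_retention_qc(blank)
  expect_equal(qcb$dice[2], 0)
  expect_true(qcb$flagged[2])

  unreg <- loss_stack(0)
  unreg$registered <- FALSE
  expect_error(dapi_retention_qc(unreg), "register")
})
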