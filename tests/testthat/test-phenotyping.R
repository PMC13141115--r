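render_disk_nucleus <- function(shape, center, radius, amp = 12000) {
  d <- sqrt(outer((seq_len(shape[1]) - center[1])^2,
                  (seq_len(shape[2]) - center[2])^2, `+`))
  amp / (1 + exp((d - radius) / 0.8))
}

test_that("nucleus segmentation finds single, touching, and many nuclei", {
  one <- mifprep:::clip_u16(render_disk_nucleus(c(64, 64), c(32, 32), 8))
  lab1 <- segment_nuclei(one)
  expect_equal(attr(lab1, "n_cells"), 1L)
  expect_lt(abs(sum(lab1 > 0) - pi * 8^2) / (pi * 8^2), 0.10)

  # two disks whose centres are 1.7 r apart (overlapping by ~30 % of r)
  two <- mifprep:::clip_u16(
    render_disk_nucleus(c(64, 64), c(32, 25), 8) +
    render_disk_nucleus(c(64, 64), c(32, 38.6), 8))
  lab2 <- segment_nuclei(two)
  expect_equal(attr(lab2, "n_cells"), 2L)

  tr <- make_scene(n_cells = 200, cycles = 1, seed = 41)
  frame <- mifprep:::clip_u16(render_frame(tr, "nuclear"))
  lab <- segment_nuclei(frame)
  n <- attr(lab, "n_cells")
  fg <- lab > 0
  cr <- tapply(row(lab)[fg], lab[fg], mean)
  cc <- tapply(col(lab)[fg], lab[fg], mean)
  dd <- outer(as.numeric(cr), tr$cells$row, `-`)^2 +
    outer(as.numeric(cc), tr$cells$col, `-`)^2
  recall <- mean(sqrt(apply(dd, 2, min)) <= 5)
  precision <- mean(sqrt(apply(dd, 1, min)) <= 5)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  expect_error(segment_nuclei(matrix(100, 30, 30)), "constant")
})

test_that("label maps export/import round-trip and relabel contiguously", {
  one <- mifprep:::clip_u16(render_disk_nucleus(c(48, 48), c(24, 24), 7))
  lab <- segment_nuclei(one)
  f <- withr::local_tempfile(fileext = ".tif")
  export_labelmap(lab, f)
  back <- import_labelmap(f, expected_shape = c(48, 48))
  expect_equal(unclass(back)[, ], unclass(lab)[, ], ignore_attr = TRUE)

  sparse <- matrix(0L, 10, 10)
  sparse[2:3, 2:3] <- 3L
  sparse[7:8, 7:8] <- 7L
  fs <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(sparse / 65535, fs, bits.per.sample = 16L,
                  compression = "none")
  rel <- import_labelmap(fs)
  expect_equal(sort(unique(as.integer(rel))), c(0L, 1L, 2L))
  expect_true(all(rel[sparse == 3] == 1) && all(rel[sparse == 7] == 2))

  ff <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.37, 8, 8), ff, bits.per.sample = 32L,
                  compression = "none")
  expect_error(import_labelmap(ff), "non-integer")
  expect_error(import_labelmap(fs, expected_shape = c(9, 9)),
               "does not match")
})

test_that("marker binarization matches the exhaustive Otsu oracle on bimodal input", {
  set.seed(19)
  px <- matrix(c(round(rnorm(600, 3000, 300)),
                 round(rnorm(424, 20000, 1500))), 32, 32)
  px <- mifprep:::clip_u16(px)
  mask <- marker_mask(px, method = "otsu")
  th <- attr(mask, "threshold")
  expect_gt(th, 4500)
  expect_lt(th, 18000)
  # same classification as the brute-force between-class-variance scan
  expect_lt(abs(mean(mask) - mean(px >= oracle_otsu(px))), 0.01)

  expect_true(all(marker_mask(px, "fixed", fixed_threshold = 0)))
  expect_false(any(marker_mask(px, "fixed", fixed_threshold = 65535 + 1)))
  expect_error(marker_mask(matrix(7, 5, 5)), "constant")
})

test_that("overlap fractions equal direct pixel counts", {
  lab <- matrix(0L, 30, 30)
  lab[3:12, 3:12] <- 1L          # 10x10 square cell
  attr(lab, "n_cells") <- 1L
  class(lab) <- c("LabelMap", class(lab))
  mask <- matrix(FALSE, 30, 30)
  mask[3:12, 3:12][seq_len(55)] <- TRUE
  expect_equal(unname(overlap_fractions(lab, mask)), 0.55)
  expect_equal(unname(overlap_fractions(lab, matrix(TRUE, 30, 30))), 1)
  expect_equal(unname(overlap_fractions(lab, matrix(FALSE, 30, 30))), 0)

  set.seed(23)
  for (trial in 1:3) {
    rl <- matrix(sample(0:5, 64 * 64, TRUE), 64, 64)
    rl <- mifprep:::relabel_filtered(rl, 1, Inf)
    rm <- matrix(sample(c(TRUE, FALSE), 64 * 64, TRUE), 64, 64)
    expect_equal(unname(overlap_fractions(rl, rm)), oracle_overlap(rl, rm))
  }
  expect_error(overlap_fractions(lab, matrix(TRUE, 5, 5)), "shapes differ")
})

test_that("identity assignment applies the 60 % rule, argmax, and the tie guard", {
  fr <- rbind(c(0.59, 0.10), c(1.0, 0.0), c(0.70, 0.90), c(0.80, 0.805),
              c(0.0, 0.0))
  colnames(fr) <- c("IBA1", "LYVE-1")
  res <- assign_identity(fr, threshold = 0.60)
  expect_equal(res$assigned_identity,
               c("unassigned", "IBA1", "LYVE-1", "unassigned", "unassigned"))
  expect_equal(res$tie_flag, c(FALSE, FALSE, FALSE, TRUE, FALSE))

  both <- assign_identity(fr, threshold = 0.60, exclusive = FALSE)
  expect_equal(both$assigned_identity[3], "IBA1;LYVE-1")

  # monotone in the threshold: raising it never gains an assignment
  set.seed(9)
  fr2 <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  assigned <- function(th) {
    assign_identity(fr2, threshold = th)$assigned_identity != "unassigned"
  }
  prev <- assigned(0.2)
  for (th in c(0.4, 0.6, 0.8, 1.0)) {
    cur <- assigned(th)
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("quantify builds a conserving cell table with valid-intensity flags", {
  tr <- make_scene(n_cells = 120, cycles = 1, seed = 51,
                   classes = c(CD68 = 0.5, `LYVE-1` = 0.5))
  nuc <- mifprep:::clip_u16(render_frame(tr, "nuclear"))
  planes <- list(image_plane(nuc))
  rows <- data.frame(cycle = 1, channel_name = "DAPI", marker = "DAPI",
                     fluorophore = "DAPI", exposure_ms = 30,
                     role = "nuclear")
  masks <- list()
  for (m in names(tr$classes)) {
    mk <- mifprep:::clip_u16(render_frame(tr, "marker", marker = m))
    planes[[length(planes) + 1]] <- image_plane(mk)
    rows <- rbind(rows, data.frame(cycle = 1, channel_name = paste0(m, "_ch"),
                                   marker = m, fluorophore = "A647",
                                   exposure_ms = 200, role = "marker"))
    masks[[m]] <- marker_mask(mk, "otsu")
  }
  hs <- assemble_hyperstack(list(list(cycle = 1, planes = planes)),
                            validate_manifest(rows))
  hs$registered <- TRUE
  labels <- segment_nuclei(nuc)
  tab <- quantify(hs, labels, masks)

  expect_equal(nrow(tab), attr(labels, "n_cells"))
  expect_equal(sum(tab$area_px), sum(labels > 0))
  expect_true(all(tab$frac_CD68 >= 0 & tab$frac_CD68 <= 1))

  # assigned identities recover the generator's memberships
  dd <- outer(tab$centroid_row, tr$cells$row, `-`)^2 +
    outer(tab$centroid_col, tr$cells$col, `-`)^2
  nn <- apply(dd, 1, which.min)
  ok <- sqrt(apply(dd, 1, min)) <= 5
  acc <- mean(tab$assigned_identity[ok] == tr$cells$class[nn[ok]])
  expect_gte(acc, 0.95)
  # validity flag marks incompatible marker intensities
  cd68 <- tab$assigned_identity == "CD68"
  expect_true(all(tab$valid_CD68[cd68]))
  expect_false(any(tab$valid_CD68[!cd68]))

  unreg <- hs; unreg$registered <- FALSE
  expect_error(quantify(unreg, labels, masks), "register")

  empty <- mifprep:::relabel_filtered(matrix(0L, nrow(nuc), ncol(nuc)))
  etab <- quantify(hs, empty, masks)
  expect_equal(nrow(etab), 0)
  expect_true(all(c("cell_id", "assigned_identity") %in% names(etab)))
})
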