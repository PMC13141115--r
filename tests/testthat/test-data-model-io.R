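test_that("single-plane TIFF round-trips losslessly and 8-bit promotes by x257", {
  set.seed(1)
  px <- matrix(sample(0:65535, 48 * 32, TRUE), 48, 32)
  f <- withr::local_tempfile(fileext = ".tif")
  write_plane(image_plane(px), f)
  back <- read_plane(f)
  expect_identical(back$pixels, px + 0)

  f8 <- withr::local_tempfile(fileext = ".tif")
  m8 <- matrix(c(0, 1, 2, 255), 2, 2)
  tiff::writeTIFF(m8 / 255, f8, bits.per.sample = 8L, compression = "none")
  expect_equal(read_plane(f8)$pixels, matrix(c(0, 257, 514, 65535), 2, 2))
})

test_that("multi-page and RGB files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(0.5, 8, 8)
  tiff::writeTIFF(list(m, m, m), f, bits.per.sample = 16L,
                  compression = "none")
  expect_error(read_plane(f), "pages=3")

  frgb <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(8, 8, 3)), frgb, bits.per.sample = 8L,
                  compression = "none")
  expect_error(read_plane(frgb), "grayscale")
  expect_error(read_plane("no/such/file.tif"), "no such image")
})

test_that("image_plane enforces range and integrality invariants", {
  expect_error(image_plane(matrix(-1, 2, 2)), "\\[0, 65535\\]")
  expect_error(image_plane(matrix(70000, 2, 2)), "\\[0, 65535\\]")
  expect_error(image_plane(matrix(0.5, 2, 2)), "integral")
  expect_error(image_plane(matrix(0, 2, 2), pixel_size = -1))
  p <- image_plane(matrix(0:3, 2, 2), pixel_size = 0.32)
  expect_equal(dim(p), c(2L, 2L))
})

manifest_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cycle,channel_name,marker,fluorophore,exposure_ms,role",
               lines), f)
  f
}

test_that("manifest validation resolves nuclear references and rejects violations", {
  ok <- read_manifest(manifest_csv(c(
    "1,DAPI,DAPI,DAPI,30,nuclear",
    "1,A647,LYVE-1,A647,200,marker",
    "2,DAPI,DAPI,DAPI,30,nuclear")))
  expect_equal(sort(unique(ok$cycle)), c(1L, 2L))
  expect_equal(ok$marker[mifprep:::nuclear_row(ok, 2)], "DAPI")

  expect_error(read_manifest(manifest_csv(c(
    "1,DAPI,DAPI,DAPI,30,nuclear",
    "2,A647,CD3,A647,200,marker"))),
    "cycle 2: no nuclear channel")
  expect_error(read_manifest(manifest_csv(c(
    "1,DAPI,DAPI,DAPI,30,nuclear",
    "1,DAPI,DAPI,DAPI,40,marker"))),
    "duplicate")
  expect_error(read_manifest(manifest_csv(c(
    "1,DAPI,DAPI,DAPI,0,nuclear"))),
    "exposure_ms")
})

test_that("a six-cycle liver panel manifest parses with one nuclear row per cycle", {
  # markers and fluorophores as used on the FFPE mouse liver panel
  panel <- c("a-SMA,A488", "MPO,A555", "CD3,A647", "CLEC4F,A647",
             "LYVE-1,A647", "IBA1,A750")
  rows <- character(0)
  for (cy in 1:6) {
    fluor <- sub(".*,", "", panel[cy])
    mk <- sub(",.*", "", panel[cy])
    rows <- c(rows, sprintf("%d,DAPI,DAPI,DAPI,30,nuclear", cy),
              sprintf("%d,%s,%s,%s,200,marker", cy, fluor, mk, fluor))
  }
  m <- read_manifest(manifest_csv(rows))
  expect_equal(length(unique(m$cycle)), 6L)
  expect_equal(sum(m$role == "nuclear"), 6L)
})

make_stack <- function(cycles = 2, markers = c("CD68", "LYVE-1"),
                       shape = c(64, 64), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cy in seq_len(cycles)) {
    rows[[length(rows) + 1]] <- data.frame(
      cycle = cy, channel_name = "DAPI", marker = "DAPI",
      fluorophore = "DAPI", exposure_ms = 30, role = "nuclear")
    for (m in markers) {
      rows[[length(rows) + 1]] <- data.frame(
        cycle = cy, channel_name = paste0(m, "_ch"), marker = m,
        fluorophore = "A647", exposure_ms = 200, role = "marker")
    }
  }
  manifest <- validate_manifest(do.call(rbind, rows))
  per_cycle <- lapply(seq_len(cycles), function(cy) {
    n <- sum(manifest$cycle == cy)
    list(cycle = cy, planes = replicate(n, image_plane(
      matrix(sample(0:65535, prod(shape), TRUE), shape[1], shape[2])),
      simplify = FALSE))
  })
  list(manifest = manifest, per_cycle = per_cycle)
}

test_that("hyperstack assembly orders planes cycle-major and validates shapes", {
  s <- make_stack(cycles = 2, markers = c("CD68", "LYVE-1"))
  hs <- assemble_hyperstack(s$per_cycle, s$manifest)
  expect_length(hs$planes, 6)
  expect_false(hs$registered)
  expect_equal(hs$records$cycle, rep(1:2, each = 3))
  # page order is strictly increasing in (cycle, manifest row)
  key <- hs$records$cycle * 100 + ave(seq_len(6), hs$records$cycle,
                                      FUN = seq_along)
  expect_true(all(diff(key) > 0))
  expect_equal(hyperstack_page_names(hs)[1:3],
               c("c1_DAPI", "c1_CD68", "c1_LYVE-1"))

  bad <- s$per_cycle
  bad[[2]]$planes[[2]] <- image_plane(matrix(0, 64, 65))
  expect_error(assemble_hyperstack(bad, s$manifest),
               "cycle 2 / CD68_ch: shape \\(64,65\\)")
  short <- s$per_cycle
  short[[1]]$planes <- short[[1]]$planes[1:2]
  expect_error(assemble_hyperstack(short, s$manifest), "manifest lists")
})

test_that("synthetic six-cycle set yields one plane per manifest row", {
  sim <- simulate_acquisition(n_cells = 40, cycles = 6, seed = 4,
                              grid = tile_grid(1, 1, 0.1, "row_major",
                                               tile_shape = c(160, 160)))
  per_cycle <- lapply(seq_len(6), function(cy) {
    list(cycle = cy,
         planes = lapply(sim$renders[[cy]], function(ch) ch$tiles[[1]]))
  })
  hs <- assemble_hyperstack(per_cycle, sim$manifest)
  # count independently from the manifest definition
  expect_length(hs$planes, nrow(sim$manifest))
  expect_equal(nrow(sim$manifest),
               6 + 1 + length(unique(sim$truth$cells$class)))
})

test_that("hyperstack container round-trips planes and records exactly", {
  s <- make_stack(cycles = 2, markers = "CD68", shape = c(32, 24), seed = 9)
  hs <- assemble_hyperstack(s$per_cycle, s$manifest)
  f <- withr::local_tempfile(fileext = ".tif")
  write_hyperstack(hs, f)
  back <- read_hyperstack(f)
  expect_length(back$planes, length(hs$planes))
  for (i in seq_along(hs$planes)) {
    expect_identical(back$planes[[i]]$pixels, hs$planes[[i]]$pixels)
  }
  expect_equal(back$records, hs$records)
  expect_false(back$registered)
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(meta$page_names, hyperstack_page_names(hs))
})
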