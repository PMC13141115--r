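# Seeded synthetic multi-cycle acquisitions with full ground truth. The
# generator emulates what the pipeline must undo: per-tile vignetting
# (shading), stage jitter between tiles, inter-cycle drift, per-cycle signal
# decay from antibody stripping, diffuse haze, autofluorescent debris,
# Poisson shot noise plus Gaussian read noise, and (chip mode) the regular
# lattice of round membrane pores. Identical seed and parameters give
# bit-identical output.

#' Generate a ground-truthed synthetic scene
#'
#' Places `n_cells` non-overlapping nuclei by rejection sampling inside the
#' mosaic frame implied by `grid`, draws a class (marker membership) per
#' cell from `classes`, and freezes every acquisition nuisance parameter
#' (per-channel shading field, per-cycle drift and retention factor,
#' per-tile jitter, haze, debris, optional pore lattice) so each pipeline
#' stage can be scored against known truth.
#'
#' @param n_cells Number of nuclei; default 400.
#' @param classes Named numeric vector of class proportions summing to 1;
#'   names are the marker names. Default two liver markers at 50/50.
#' @param cycles Number of staining cycles; default 6.
#' @param grid The acquisition [tile_grid()]; default 2 x 2 tiles of
#'   232 x 232 px with 10 % overlap.
#' @param radius_range Nuclear radius range in pixels; default 4--6.
#' @param margin Cell-free border of the frame, px; default 20.
#' @param drift_max Largest per-cycle stage drift (integer px, per axis);
#'   default 8. Cycle 1 has zero drift.
#' @param jitter_max Largest per-tile placement jitter (integer px);
#'   default 3.
#' @param retention_base Per-cycle multiplicative signal retention;
#'   cycle k is scaled by `retention_base^(k-1)`. Default 0.95.
#' @param shading_strength Vignette depth of the per-channel shading field
#'   (corner attenuation relative to centre); default 0.25.
#' @param haze_amplitude Amplitude of the broad background haze; default
#'   800 intensity units.
#' @param n_debris Autofluorescent debris blobs; default 25.
#' @param sigma_read Gaussian read-noise standard deviation; default 2.
#' @param af_leak Fraction of the debris (autofluorescence) signal leaking
#'   into marker channels; default 0.3.
#' @param pores `NULL`, or `list(spacing =, radius =)` in px to add the
#'   chip-membrane pore lattice to every channel.
#' @param loss_fraction Per-cycle fraction of nuclei missing from cycles
#'   after the first (synthetic tissue loss); default 0.
#' @param seed Master seed; all randomness derives from it.
#' @return A `SceneTruth` list: `cells` data.frame (`id`, `row`, `col`,
#'   `radius`, `class`), frame `shape`, `grid`, per-cycle `drifts` and
#'   `retention`, per-cycle-per-tile `jitters`, shading/haze/debris/pore
#'   parameters, and the seed.
#' @export
make_scene <- function(n_cells = 400,
                       classes = c("LYVE-1" = 0.5, "IBA1" = 0.5),
                       cycles = 6,
                       grid = tile_grid(2, 2, 0.1, "row_major",
                                        tile_shape = c(232, 232)),
                       radius_range = c(4, 6),
                       margin = 20,
                       drift_max = 8,
                       jitter_max = 3,
                       retention_base = 0.95,
                       shading_strength = 0.25,
                       haze_amplitude = 800,
                       n_debris = 25,
                       af_leak = 0.3,
                       sigma_read = 2,
                       pores = NULL,
                       loss_fraction = 0,
                       seed = 1) {
  stopifnot(n_cells >= 0, cycles >= 1, inherits(grid, "TileGrid"))
  if (abs(sum(classes) - 1) > 1e-8) stop("class proportions must sum to 1")
  shape <- mosaic_extent(grid)
  avail <- prod(shape - 2 * margin)
  demand <- n_cells * pi * mean(radius_range)^2
  if (demand > 0.6 * avail) {
    stop(sprintf("infeasible packing: %d cells demand %.0f px^2, > 60%% of frame",
                 n_cells, demand))
  }
  set.seed(seed)
  cells <- place_cells(n_cells, shape, radius_range, margin)
  cells$class <- if (n_cells > 0) {
    sample(names(classes), n_cells, replace = TRUE, prob = classes)
  } else {
    character(0)
  }
  drifts <- cbind(dy = c(0, sample(-drift_max:drift_max, cycles - 1, TRUE)),
                  dx = c(0, sample(-drift_max:drift_max, cycles - 1, TRUE)))
  n_tiles <- grid$rows * grid$cols
  jitters <- array(sample(-jitter_max:jitter_max, cycles * n_tiles * 2, TRUE),
                   dim = c(cycles, n_tiles, 2))
  jitters[1, 1, ] <- 0L   # anchor tile of the reference cycle
  haze <- list(amplitude = haze_amplitude,
               center = c(runif(1, 0.3, 0.7) * shape[1],
                          runif(1, 0.3, 0.7) * shape[2]),
               sigma = 0.45 * max(shape))
  debris <- data.frame(row = runif(n_debris, 1, shape[1]),
                       col = runif(n_debris, 1, shape[2]),
                       radius = runif(n_debris, 2, 5),
                       amplitude = runif(n_debris, 4000, 12000))
  lost <- matrix(FALSE, cycles, max(1, n_cells))
  if (loss_fraction > 0 && n_cells > 0) {
    for (k in 2:cycles) {
      lost[k, sample(n_cells, round(loss_fraction * n_cells))] <- TRUE
    }
  }
  structure(list(cells = cells, classes = classes, shape = shape,
                 grid = grid, cycles = as.integer(cycles),
                 drifts = drifts,
                 retention = retention_base^(seq_len(cycles) - 1),
                 jitters = jitters,
                 shading_strength = shading_strength,
                 haze = haze, debris = debris, af_leak = af_leak,
                 sigma_read = sigma_read, pores = pores,
                 lost = lost, seed = as.integer(seed)),
            class = "SceneTruth")
}

#' @export
print.SceneTruth <- function(x, ...) {
  cat(sprintf("<SceneTruth %d cells (%s), %d cycles, frame %d x %d, seed %d>\n",
              nrow(x$cells),
              paste(names(x$classes), collapse = "/"),
              x$cycles, x$shape[1], x$shape[2], x$seed))
  invisible(x)
}

# Full mosaic extent of a tile grid (height, width).
mosaic_extent <- function(grid) {
  sp_r <- round_half_up(grid$tile_shape[1] * (1 - grid$overlap_fraction))
  sp_c <- round_half_up(grid$tile_shape[2] * (1 - grid$overlap_fraction))
  c((grid$rows - 1) * sp_r + grid$tile_shape[1],
    (grid$cols - 1) * sp_c + grid$tile_shape[2])
}

# Rejection-sample non-overlapping nuclei (centre gap >= r_i + r_j + 2).
place_cells <- function(n_cells, shape, radius_range, margin) {
  rows <- numeric(n_cells); cols <- numeric(n_cells); rad <- numeric(n_cells)
  placed <- 0L
  attempts <- 0L
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 200 * max(1, n_cells)) {
      stop("rejection sampling failed; scene too crowded")
    }
    r <- runif(1, radius_range[1], radius_range[2])
    y <- runif(1, margin + r, shape[1] - margin - r)
    x <- runif(1, margin + r, shape[2] - margin - r)
    if (placed > 0) {
      i <- seq_len(placed)
      if (any((rows[i] - y)^2 + (cols[i] - x)^2 <
              (rad[i] + r + 2)^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- y; cols[placed] <- x; rad[placed] <- r
  }
  data.frame(id = seq_len(n_cells), row = rows, col = cols, radius = rad)
}

# Accumulate radially symmetric blobs into `frame`. `profile` maps the
# distance-to-centre (vector) and radius (scalar) to intensity.
draw_blobs <- function(frame, rows, cols, radii, amplitudes, profile,
                       support = 3) {
  H <- nrow(frame); W <- ncol(frame)
  for (i in seq_along(rows)) {
    r <- radii[i]
    ext <- ceiling(support + r * 2)
    y0 <- max(1, floor(rows[i] - ext)); y1 <- min(H, ceiling(rows[i] + ext))
    x0 <- max(1, floor(cols[i] - ext)); x1 <- min(W, ceiling(cols[i] + ext))
    if (y0 > y1 || x0 > x1) next
    d <- sqrt(outer((y0:y1 - rows[i])^2, (x0:x1 - cols[i])^2, `+`))
    frame[y0:y1, x0:x1] <- frame[y0:y1, x0:x1] +
      amplitudes[i] * profile(d, r)
  }
  frame
}

# Soft-edged disk: ~1 inside radius r, logistic falloff of width `edge`.
soft_disk <- function(d, r, edge = 0.8) 1 / (1 + exp((d - r) / edge))

#' Render the noiseless full-frame image of one channel
#'
#' Reference-frame (cycle-1, unshaded, unshifted) rendering: nuclei as
#' soft-edged Gaussian-profile blobs on the nuclear channel; each marker
#' over its member cells' footprints dilated by 3 px (emulating membrane
#' staining that covers the nucleus in 2-D projection, with a brighter
#' rim); debris blobs on the autofluorescence channel. Chip mode
#' superimposes the pore lattice.
#'
#' @param truth A `SceneTruth`.
#' @param role `"nuclear"`, `"marker"` or `"autofluorescence"`.
#' @param marker Marker name (for `role = "marker"`).
#' @param cycle Cycle index (applies synthetic tissue loss, if any).
#' @return Noiseless intensity matrix (not yet an `ImagePlane`).
#' @export
render_frame <- function(truth, role, marker = NULL, cycle = 1L) {
  frame <- matrix(0, truth$shape[1], truth$shape[2])
  cells <- truth$cells
  if (nrow(cells) > 0 && truth$cycles >= cycle) {
    cells <- cells[!truth$lost[cycle, cells$id], , drop = FALSE]
  }
  if (role == "nuclear" && nrow(cells) > 0) {
    frame <- draw_blobs(frame, cells$row, cells$col, cells$radius,
                        rep(12000, nrow(cells)),
                        function(d, r) soft_disk(d, r))
  } else if (role == "marker") {
    stopifnot(!is.null(marker))
    mem <- cells[cells$class == marker, , drop = FALSE]
    if (nrow(mem) > 0) {
      frame <- draw_blobs(frame, mem$row, mem$col, mem$radius,
                          rep(14000, nrow(mem)),
                          function(d, r) {
                            body <- 0.75 * soft_disk(d, r + 3)
                            rim <- 0.45 * exp(-(d - (r + 2))^2 / 2)
                            body + rim
                          })
    }
    deb <- truth$debris
    if ((truth$af_leak %||% 0) > 0 && nrow(deb) > 0) {
      frame <- draw_blobs(frame, deb$row, deb$col, deb$radius,
                          truth$af_leak * deb$amplitude,
                          function(d, r) soft_disk(d, r))
    }
  } else if (role == "autofluorescence") {
    deb <- truth$debris
    if (nrow(deb) > 0) {
      frame <- draw_blobs(frame, deb$row, deb$col, deb$radius,
                          deb$amplitude, function(d, r) soft_disk(d, r))
    }
  }
  if (!is.null(truth$pores)) {
    frame <- frame + render_pores(truth$shape, truth$pores)
  }
  frame
}

# Regular lattice of small, perfectly round pores (membrane chips).
render_pores <- function(shape, pores) {
  sp <- pores$spacing
  centers <- expand.grid(row = seq(sp / 2, shape[1], by = sp),
                         col = seq(sp / 2, shape[2], by = sp))
  draw_blobs(matrix(0, shape[1], shape[2]), centers$row, centers$col,
             rep(pores$radius, nrow(centers)),
             rep(pores$amplitude %||% 3000, nrow(centers)),
             function(d, r) soft_disk(d, r, edge = 0.4))
}

# The vignette shading field for one channel, tile-shaped, mean 1. A mild
# per-channel phase offset makes fields channel-specific but reproducible.
scene_shading_field <- function(truth, channel_index = 1L) {
  H <- truth$grid$tile_shape[1]; W <- truth$grid$tile_shape[2]
  cy <- (H + 1) / 2 + 3 * (channel_index - 1)
  cx <- (W + 1) / 2 - 2 * (channel_index - 1)
  d2 <- outer(((seq_len(H) - cy) / H)^2, ((seq_len(W) - cx) / W)^2, `+`)
  f <- 1 - truth$shading_strength * d2 / max(d2)
  f / mean(f)
}

# The broad background haze (diffuse out-of-focus light), reference frame.
scene_haze <- function(truth) {
  h <- truth$haze
  d2 <- outer((seq_len(truth$shape[1]) - h$center[1])^2,
              (seq_len(truth$shape[2]) - h$center[2])^2, `+`)
  h$amplitude * exp(-d2 / (2 * h$sigma^2))
}

#' Render the acquired tiles of one cycle
#'
#' Applies, in order: per-cycle retention scaling, haze, per-cycle drift,
#' cutting into per-tile rasters at jittered origins, per-tile shading
#' multiplication, and Poisson shot noise plus Gaussian read noise. Noise
#' is seeded deterministically from the master seed, cycle and channel.
#'
#' @param truth A `SceneTruth`.
#' @param cycle Cycle index (1-based).
#' @param records Manifest rows of this cycle (see [scene_manifest()]).
#' @param noise Disable to obtain the clean acquisition.
#' @return List with one element per record: `record` (manifest row),
#'   `tiles` (list of `ImagePlane` in acquisition order) and `frame`
#'   (clean drift-applied mosaic-frame matrix, before shading and noise).
#' @export
render_cycle <- function(truth, cycle, records, noise = TRUE) {
  stopifnot(cycle >= 1, cycle <= truth$cycles)
  grid <- truth$grid
  pl <- nominal_positions(grid)
  out <- vector("list", nrow(records))
  for (k in seq_len(nrow(records))) {
    rec <- records[k, ]
    base <- render_frame(truth, rec$role, marker = rec$marker, cycle = cycle)
    base <- base * truth$retention[cycle]
    if (rec$role != "brightfield") base <- base + scene_haze(truth)
    drifted <- translate_pixels(base, -truth$drifts[cycle, "dy"],
                                -truth$drifts[cycle, "dx"], fill = 0)
    field <- scene_shading_field(truth, channel_index = k)
    if (noise) set.seed(truth$seed + 7919L * cycle + 131L * k)
    tiles <- vector("list", nrow(pl))
    H <- grid$tile_shape[1]; W <- grid$tile_shape[2]
    for (t in seq_len(nrow(pl))) {
      acq <- pl$tile[t]
      oy <- pl$nom_row[t] + truth$jitters[cycle, acq, 1]
      ox <- pl$nom_col[t] + truth$jitters[cycle, acq, 2]
      tile <- cut_window(drifted, oy, ox, H, W)
      tile <- tile * field
      if (noise) {
        tile <- rpois_cap(tile) + stats::rnorm(length(tile), 0,
                                               truth$sigma_read)
      }
      tiles[[acq]] <- image_plane(clip_u16(tile))
    }
    out[[k]] <- list(record = rec, tiles = tiles, frame = base)
  }
  out
}

# Extract an H x W window at 0-based origin (oy, ox); outside = 0.
cut_window <- function(frame, oy, ox, H, W) {
  out <- matrix(0, H, W)
  src_r <- (oy + 1):(oy + H)
  src_c <- (ox + 1):(ox + W)
  ok_r <- src_r >= 1 & src_r <= nrow(frame)
  ok_c <- src_c >= 1 & src_c <= ncol(frame)
  out[ok_r, ok_c] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

# Poisson draw, vectorized over a matrix of means, preserving shape.
rpois_cap <- function(m) {
  matrix(stats::rpois(length(m), pmin(as.numeric(m), 1e6)), nrow(m), ncol(m))
}

#' Default manifest of a synthetic scene
#'
#' Every cycle carries the nuclear (DAPI) reference; the scene's markers
#' are spread over the earliest cycles (one per cycle starting at cycle 2,
#' wrapping if there are more markers than cycles); cycle 1 additionally
#' records the autofluorescence channel when `autofluorescence = TRUE`.
#'
#' @param truth A `SceneTruth`.
#' @param autofluorescence Include an autofluorescence channel; default
#'   `TRUE`.
#' @return A validated manifest `data.frame`.
#' @export
scene_manifest <- function(truth, autofluorescence = TRUE) {
  fluors <- c("A488", "A555", "A647", "A750")
  rows <- list()
  markers <- names(truth$classes)
  for (cy in seq_len(truth$cycles)) {
    rows[[length(rows) + 1L]] <- data.frame(
      cycle = cy, channel_name = "DAPI", marker = "DAPI",
      fluorophore = "DAPI", exposure_ms = 30, role = "nuclear")
    if (cy == 1 && autofluorescence) {
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = cy, channel_name = "AF488", marker = "AF",
        fluorophore = "A488", exposure_ms = 100, role = "autofluorescence")
    }
    mk <- which((seq_along(markers) %% truth$cycles) + 1L == cy)
    for (m in mk) {
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = cy, channel_name = fluors[(m - 1) %% length(fluors) + 1L],
        marker = markers[m],
        fluorophore = fluors[(m - 1) %% length(fluors) + 1L],
        exposure_ms = 200, role = "marker")
    }
  }
  validate_manifest(do.call(rbind, rows))
}

#' Simulate a full acquisition and (optionally) write it to disk
#'
#' One-call generator used by the test-suite and the CLI: builds the scene,
#' renders every cycle, and, when `out_dir` is given, writes the fixture in
#' the pipeline's expected on-disk layout (tiles, shading references,
#' manifest, scene description, ground-truth tables).
#'
#' @param preset `"tissue"` (default), `"cells2d"` (fewer, larger cells,
#'   more debris) or `"chip"` (adds the membrane pore lattice).
#' @param n_cells,cycles,seed Passed to [make_scene()].
#' @param out_dir Optional fixture directory.
#' @param ... Further arguments to [make_scene()].
#' @return List with `truth`, `manifest`, `renders` (per cycle, see
#'   [render_cycle()]) and, if written, `dir`.
#' @export
simulate_acquisition <- function(preset = c("tissue", "cells2d", "chip"),
                                 n_cells = 400, cycles = 6, seed = 1,
                                 out_dir = NULL, ...) {
  preset <- match.arg(preset)
  extra <- list(...)
  args <- list(n_cells = n_cells, cycles = cycles, seed = seed)
  if (preset == "cells2d") {
    args$radius_range <- c(6, 9)
    args$n_debris <- 50
  } else if (preset == "chip") {
    args$pores <- list(spacing = 24, radius = 4, amplitude = 3000)
  }
  args[names(extra)] <- extra
  truth <- do.call(make_scene, args)
  manifest <- scene_manifest(truth)
  renders <- lapply(seq_len(truth$cycles), function(cy) {
    render_cycle(truth, cy, manifest[manifest$cycle == cy, , drop = FALSE])
  })
  sim <- list(truth = truth, manifest = manifest, renders = renders)
  if (!is.null(out_dir)) {
    write_fixture(sim, out_dir)
    sim$dir <- out_dir
  }
  sim
}

#' Write a simulated acquisition as an on-disk fixture
#'
#' Layout: `manifest.csv`, `scene.json` (grid and generator parameters),
#' `truth_cells.csv` and `truth_drifts.csv` (ground truth),
#' `shading/<channel_name>.tif` (synthetic shading reference per channel),
#' and `tiles/c<cycle>_<channel_name>_t<k>.tif` for every tile in
#' acquisition order -- exactly what [run_pipeline()] consumes.
#'
#' @param sim Result of [simulate_acquisition()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  truth <- sim$truth
  dir.create(file.path(dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "shading"), recursive = TRUE,
             showWarnings = FALSE)
  write_manifest(sim$manifest, file.path(dir, "manifest.csv"))
  utils::write.csv(truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cycle = seq_len(truth$cycles),
                              dy = truth$drifts[, "dy"],
                              dx = truth$drifts[, "dx"],
                              retention = truth$retention),
                   file.path(dir, "truth_drifts.csv"), row.names = FALSE)
  grid <- truth$grid
  scene <- list(grid = list(rows = grid$rows, cols = grid$cols,
                            overlap_fraction = grid$overlap_fraction,
                            acquisition_order = grid$acquisition_order,
                            tile_shape = grid$tile_shape),
                cycles = truth$cycles, seed = truth$seed,
                shape = truth$shape, classes = as.list(truth$classes),
                sigma_read = truth$sigma_read)
  jsonlite::write_json(scene, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  written_fields <- character(0)
  for (cy in seq_along(sim$renders)) {
    for (ch in sim$renders[[cy]]) {
      rec <- ch$record
      cyc_names <- sim$manifest$channel_name[sim$manifest$cycle == cy]
      field <- scene_shading_field(truth,
                                   channel_index = match(rec$channel_name,
                                                         cyc_names))
      if (!rec$channel_name %in% written_fields) {
        ref <- clip_u16(20000 * field)
        write_plane(image_plane(ref),
                    file.path(dir, "shading",
                              paste0(rec$channel_name, ".tif")))
        written_fields <- c(written_fields, rec$channel_name)
      }
      for (t in seq_along(ch$tiles)) {
        write_plane(ch$tiles[[t]],
                    file.path(dir, "tiles",
                              sprintf("c%d_%s_t%02d.tif", cy,
                                      rec$channel_name, t)))
      }
    }
  }
  invisible(dir)
}
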