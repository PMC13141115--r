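# Mosaic stitching: nominal placement from the grid geometry, pairwise
# translation refinement by phase correlation on the overlap strips, global
# placement along a maximum-correlation spanning tree, feathered blending.

#' Nominal tile placements from grid geometry
#'
#' Tile (r, c) of the grid nominally sits at origin
#' `(r * H * (1 - ov), c * W * (1 - ov))` (rounded half-up to integers),
#' where `(H, W)` is the tile shape and `ov` the overlap fraction. Snake
#' acquisition order is remapped so placements are listed row-major.
#'
#' @param grid A [tile_grid()].
#' @return A `TilePlacements` object: `data.frame` in row-major grid order
#'   with columns `tile` (acquisition index), `grid_row`, `grid_col`,
#'   `nom_row`, `nom_col`, `ref_row`, `ref_col` (refined origin, initially
#'   nominal) and `flagged`; attribute `pairs` holds per-pair scores after
#'   [refine_offsets()].
#' @export
nominal_positions <- function(grid) {
  stopifnot(inherits(grid, "TileGrid"))
  cells <- grid_cells(grid)
  cells <- cells[order(cells$grid_row, cells$grid_col), ]
  H <- grid$tile_shape[1]; W <- grid$tile_shape[2]
  ov <- grid$overlap_fraction
  pl <- data.frame(tile = cells$tile,
                   grid_row = cells$grid_row, grid_col = cells$grid_col,
                   nom_row = round_half_up(cells$grid_row * H * (1 - ov)),
                   nom_col = round_half_up(cells$grid_col * W * (1 - ov)))
  pl$ref_row <- pl$nom_row
  pl$ref_col <- pl$nom_col
  pl$flagged <- FALSE
  rownames(pl) <- NULL
  attr(pl, "pairs") <- data.frame()
  class(pl) <- c("TilePlacements", "data.frame")
  pl
}

# Overlap strips of an adjacent pair under nominal placement. `a` and `b`
# are placement rows with b right of / below a.
overlap_strips <- function(tile_a, tile_b, axis, ov_px) {
  H <- nrow(tile_a); W <- ncol(tile_a)
  if (axis == "col") {
    list(a = tile_a[, (W - ov_px + 1):W, drop = FALSE],
         b = tile_b[, 1:ov_px, drop = FALSE])
  } else {
    list(a = tile_a[(H - ov_px + 1):H, , drop = FALSE],
         b = tile_b[1:ov_px, , drop = FALSE])
  }
}

# Translation between two nominally aligned strips by exhaustive normalized
# cross-correlation over the +-search window, with parabolic subpixel
# refinement quantized to 1/upsample px. Returns s with B(x) = A(x - s),
# like estimate_shift(). Narrow overlap strips carry too little spectral
# support for whitened phase correlation, so the search is done in the
# spatial domain where the correlation is weighted by actual content.
strip_offset <- function(A, B, search, upsample = 10L) {
  shifts_y <- -search[1]:search[1]
  shifts_x <- -search[2]:search[2]
  surf <- matrix(-Inf, length(shifts_y), length(shifts_x))
  for (iy in seq_along(shifts_y)) {
    for (ix in seq_along(shifts_x)) {
      surf[iy, ix] <- aligned_correlation(A, B,
                                          c(shifts_y[iy], shifts_x[ix]))
    }
  }
  p <- arrayInd(which.max(surf), dim(surf))
  best <- c(shifts_y[p[1]], shifts_x[p[2]])
  corr <- surf[p[1], p[2]]
  # parabolic refinement per axis where interior; ties/plateaus give 0
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (cm - cp) / den
    max(min(d, 0.5), -0.5)
  }
  sub <- c(0, 0)
  if (p[1] > 1 && p[1] < nrow(surf)) {
    sub[1] <- refine(surf[p[1] - 1, p[2]], corr, surf[p[1] + 1, p[2]])
  }
  if (p[2] > 1 && p[2] < ncol(surf)) {
    sub[2] <- refine(surf[p[1], p[2] - 1], corr, surf[p[1], p[2] + 1])
  }
  s <- best + round(sub * upsample) / upsample
  list(dy = s[1], dx = s[2], corr = if (is.finite(corr)) corr else 0)
}

#' Refine tile placements on the overlap strips
#'
#' For each adjacent tile pair the translation between the two nominal
#' overlap strips is estimated by exhaustive normalized cross-correlation
#' over the stage-jitter search window with parabolic subpixel refinement
#' (narrow strips carry too little spectral support for whitened phase
#' correlation, so the search is spatial and content-weighted); the quality
#' score is the Pearson correlation of the aligned strips. Global
#' placements anchor the
#' top-left tile at its nominal origin and accumulate pairwise offsets along
#' the maximum-correlation spanning tree of the pair graph. Pairs scoring
#' below `min_correlation` fall back to their nominal offset and are
#' flagged.
#'
#' @param tiles List of `ImagePlane`s/matrices in acquisition order.
#' @param grid The [tile_grid()]; `length(tiles)` must equal `rows * cols`.
#' @param min_correlation Pairs below this score use the nominal offset;
#'   default 0.3.
#' @param upsample Subpixel refinement factor; default 10.
#' @return A `TilePlacements` object (see [nominal_positions()]) with
#'   refined origins and the per-pair table in `attr(, "pairs")`.
#' @export
refine_offsets <- function(tiles, grid, min_correlation = 0.3,
                           upsample = 10L) {
  stopifnot(inherits(grid, "TileGrid"))
  if (length(tiles) != grid$rows * grid$cols) {
    stop(sprintf("%d tiles supplied for a %d x %d grid",
                 length(tiles), grid$rows, grid$cols))
  }
  mats <- lapply(tiles, plane_pixels)
  pl <- nominal_positions(grid)
  H <- grid$tile_shape[1]; W <- grid$tile_shape[2]
  # overlap in pixels along each axis, from the nominal spacing
  spacing_r <- round_half_up(H * (1 - grid$overlap_fraction))
  spacing_c <- round_half_up(W * (1 - grid$overlap_fraction))
  ov_r <- H - spacing_r
  ov_c <- W - spacing_c
  if ((grid$rows > 1 && ov_r < 8) || (grid$cols > 1 && ov_c < 8)) {
    stop(sprintf("overlap strip too small (%d x %d px); need >= 8 px",
                 ov_r, ov_c))
  }
  key <- function(r, c) which(pl$grid_row == r & pl$grid_col == c)
  pairs <- list()
  for (i in seq_len(nrow(pl))) {
    r <- pl$grid_row[i]; c <- pl$grid_col[i]
    for (dirn in c("col", "row")) {
      j <- if (dirn == "col") key(r, c + 1) else key(r + 1, c)
      if (!length(j)) next
      ov_px <- if (dirn == "col") ov_c else ov_r
      st <- overlap_strips(mats[[pl$tile[i]]], mats[[pl$tile[j]]],
                           dirn, ov_px)
      nominal_rel <- c(pl$nom_row[j] - pl$nom_row[i],
                       pl$nom_col[j] - pl$nom_col[i])
      # search range: keep at least 2 px of common strip along the narrow
      # axis; along the long axis allow the same magnitude
      rng <- max(3L, ov_px - 2L)
      meas <- strip_offset(st$a, st$b, search = c(rng, rng),
                           upsample = upsample)
      # strip B equals strip A shifted by -delta, where delta is the true
      # relative origin minus the nominal one
      delta <- -c(meas$dy, meas$dx)
      fallback <- meas$corr < min_correlation
      pairs[[length(pairs) + 1L]] <- data.frame(
        from = i, to = j, axis = dirn,
        rel_row = if (fallback) nominal_rel[1] else nominal_rel[1] + delta[1],
        rel_col = if (fallback) nominal_rel[2] else nominal_rel[2] + delta[2],
        correlation = meas$corr,
        fallback = fallback)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else data.frame()
  if (nrow(pl) > 1 && nrow(pairs) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs$from, to = pairs$to,
                 weight = 1 - pairs$correlation,
                 pair = seq_len(nrow(pairs))),
      directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(pl))))
    tree <- igraph::mst(g)
    root <- key(0, 0)
    bfs <- igraph::bfs(tree, root = root, father = TRUE,
                       unreachable = FALSE)
    order_v <- as.integer(bfs$order)
    father <- as.integer(bfs$father)
    origin <- cbind(pl$nom_row, pl$nom_col) * NA_real_
    origin[root, ] <- c(pl$nom_row[root], pl$nom_col[root])
    flagged <- rep(FALSE, nrow(pl))
    for (v in order_v) {
      if (v == root || is.na(v)) next
      f <- father[v]
      e <- igraph::get_edge_ids(tree, c(f, v))
      pair_id <- igraph::edge_attr(tree, "pair", e)
      pr <- pairs[pair_id, ]
      sgn <- if (pr$from == f) 1 else -1
      origin[v, ] <- origin[f, ] + sgn * c(pr$rel_row, pr$rel_col)
      flagged[v] <- flagged[f] || pr$fallback
    }
    miss <- is.na(origin[, 1])
    origin[miss, ] <- cbind(pl$nom_row, pl$nom_col)[miss, ]
    pl$ref_row <- origin[, 1]
    pl$ref_col <- origin[, 2]
    pl$flagged <- flagged | miss
  }
  attr(pl, "pairs") <- pairs
  pl
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Blend placed tiles into one mosaic
#'
#' The canvas is the bounding box of all placed tiles. Where a single tile
#' covers a pixel the output copies it bit-exactly; in overlaps, tiles are
#' feathered linearly with weights proportional to each pixel's distance to
#' its tile's nearest edge (normalized to sum 1). Fractional origins are
#' resampled bilinearly onto the integer canvas grid; integer origins are
#' placed exactly. Uncovered canvas is 0.
#'
#' @param tiles List of `ImagePlane`s/matrices in acquisition order.
#' @param placements A `TilePlacements` object ([nominal_positions()] or
#'   [refine_offsets()]).
#' @return The mosaic as an `ImagePlane`; attribute `"coverage"` is the
#'   logical matrix of canvas pixels covered by at least one tile.
#' @export
blend_mosaic <- function(tiles, placements) {
  stopifnot(inherits(placements, "TilePlacements"))
  mats <- lapply(tiles, plane_pixels)
  pz <- if (is_image_plane(tiles[[1]])) tiles[[1]]$pixel_size else NULL
  or_r <- placements$ref_row - min(placements$ref_row)
  or_c <- placements$ref_col - min(placements$ref_col)
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  canvas_h <- as.integer(ceiling(max(or_r + H)))
  canvas_w <- as.integer(ceiling(max(or_c + W)))
  num <- matrix(0, canvas_h, canvas_w)
  den <- matrix(0, canvas_h, canvas_w)
  eps <- 1e-9
  for (k in seq_len(nrow(placements))) {
    m <- mats[[placements$tile[k]]]
    oy <- or_r[k]; ox <- or_c[k]
    int_place <- abs(oy - round(oy)) < eps && abs(ox - round(ox)) < eps
    if (int_place) {
      oy <- round(oy); ox <- round(ox)
      rows <- (oy + 1):(oy + H)
      cols <- (ox + 1):(ox + W)
      d <- outer(pmin(seq_len(H), H + 1 - seq_len(H)),
                 pmin(seq_len(W), W + 1 - seq_len(W)), pmin)
      num[rows, cols] <- num[rows, cols] + d * m
      den[rows, cols] <- den[rows, cols] + d
    } else {
      rows <- (floor(oy) + 1):(floor(oy) + H)
      cols <- (floor(ox) + 1):(floor(ox) + W)
      rows <- rows[rows >= 1 & rows <= canvas_h]
      cols <- cols[cols >= 1 & cols <= canvas_w]
      ly <- rows - oy          # tile-local coordinates, 1-based
      lx <- cols - ox
      keep_y <- ly >= 1 & ly <= H
      keep_x <- lx >= 1 & lx <= W
      rows <- rows[keep_y]; ly <- ly[keep_y]
      cols <- cols[keep_x]; lx <- lx[keep_x]
      if (!length(rows) || !length(cols)) next
      Rg <- matrix(ly, length(ly), length(lx))
      Cg <- matrix(rep(lx, each = length(ly)), length(ly), length(lx))
      vals <- matrix(sample_bilinear(m, as.numeric(Rg), as.numeric(Cg)),
                     length(ly), length(lx))
      d <- outer(pmin(ly, H + 1 - ly), pmin(lx, W + 1 - lx), pmin)
      num[rows, cols] <- num[rows, cols] + d * vals
      den[rows, cols] <- den[rows, cols] + d
    }
  }
  out <- num
  covered <- den > 0
  out[covered] <- num[covered] / den[covered]
  out[!covered] <- 0
  res <- image_plane(clip_u16(out), pixel_size = pz)
  attr(res, "coverage") <- covered
  res
}

#' Stitch a full tile set in one call
#'
#' Convenience wrapper: [refine_offsets()] (optional) then [blend_mosaic()].
#'
#' @inheritParams refine_offsets
#' @param refine Estimate placements from the image content (default) or
#'   use nominal grid positions only.
#' @return List with `mosaic` (`ImagePlane`) and `placements`.
#' @export
stitch_tiles <- function(tiles, grid, refine = TRUE, min_correlation = 0.3,
                         upsample = 10L) {
  pl <- if (refine) {
    refine_offsets(tiles, grid, min_correlation = min_correlation,
                   upsample = upsample)
  } else {
    nominal_positions(grid)
  }
  list(mosaic = blend_mosaic(tiles, pl), placements = pl)
}
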