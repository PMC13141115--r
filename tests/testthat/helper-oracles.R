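# Independent brute-force oracles used to pin down expected values.

# Grayscale opening with the ball cap by direct per-pixel min/max, with
# out-of-domain offsets ignored (mirrors the documented boundary rule but
# shares no code with the package kernel).
oracle_ball_opening <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  z <- sqrt(r^2 - off$di^2 - off$dj^2)
  di <- off$di; dj <- off$dj
  er <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
      er[i, j] <- min(img[cbind(ii[ok], jj[ok])] - z[ok])
    }
  }
  dl <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
      dl[i, j] <- max(er[cbind(ii[ok], jj[ok])] + z[ok])
    }
  }
  dl
}

# Otsu's threshold by exhaustive scan of the between-class variance over
# every distinct intensity cut.
oracle_otsu <- function(px) {
  v <- sort(unique(as.numeric(px)))
  best <- -Inf; best_t <- v[1]
  n <- length(px)
  for (t in v[-1]) {
    lo <- px < t
    w0 <- sum(lo) / n
    if (w0 == 0 || w0 == 1) next
    bc <- w0 * (1 - w0) * (mean(px[lo]) - mean(px[!lo]))^2
    if (bc > best) {
      best <- bc
      best_t <- t
    }
  }
  best_t
}

# Per-cell overlap fractions by direct pixel counting.
oracle_overlap <- function(labels, mask) {
  n <- max(labels)
  out <- numeric(n)
  for (k in seq_len(n)) {
    cell <- labels == k
    out[k] <- sum(cell & mask) / sum(cell)
  }
  out
}

# A small textured nuclear frame used across registration/stitching tests.
textured_frame <- function(n_cells = 150, seed = 3, grid = NULL, offset = 200) {
  args <- list(n_cells = n_cells, cycles = 1, seed = seed)
  if (!is.null(grid)) args$grid <- grid
  tr <- do.call(make_scene, args)
  list(truth = tr,
       pixels = pmin(render_frame(tr, "nuclear") + offset, 65535))
}

# Draw a hard disk of the given radius into a matrix (used to build label
# and mask fixtures with exactly known geometry).
disk_mask <- function(shape, center, radius) {
  d2 <- outer((seq_len(shape[1]) - center[1])^2,
              (seq_len(shape[2]) - center[2])^2, `+`)
  d2 <= radius^2
}
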