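# Internal numeric helpers shared across stages.

U16_MAX <- 65535

# Round half away from zero (inputs are nonnegative here, so half-up),
# unlike base round() which rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

# Clip to the unsigned 16-bit range, then round; order matters so that
# rounding can never push a value past the range again.
clip_u16 <- function(x) {
  x <- round_half_up(x)
  x[x < 0] <- 0
  x[x > U16_MAX] <- U16_MAX
  x
}

# Symmetric (mirror) padding indices for a dimension of size n and pad r.
# Uses the edge-inclusive reflection a b c -> b a | a b c | c b; requires
# r <= n, which callers guarantee by capping kernel radii.
reflect_indices <- function(n, r) {
  if (r == 0) return(seq_len(n))
  c(r:1, seq_len(n), n:(n - r + 1))
}

# Separable Gaussian smoothing with reflective boundaries. Kernel radius is
# 3*sigma, capped below the image extent so reflection stays single-fold.
gaussian_smooth <- function(mat, sigma) {
  stopifnot(sigma > 0)
  smooth_dim1 <- function(m, sigma) {
    n <- nrow(m)
    r <- min(ceiling(3 * sigma), n - 1L)
    if (r < 1) return(m)
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    k <- k / sum(k)
    pad <- m[reflect_indices(n, r), , drop = FALSE]
    f <- stats::filter(pad, k, sides = 2)
    matrix(f[(r + 1):(r + n), ], n, ncol(m))
  }
  t(smooth_dim1(t(smooth_dim1(mat, sigma)), sigma))
}

# 3x3 box mean with reflective boundaries (used for local-contrast weights).
box_mean3 <- function(mat) {
  smooth_dim1 <- function(m) {
    n <- nrow(m)
    pad <- m[reflect_indices(n, 1L), , drop = FALSE]
    f <- stats::filter(pad, rep(1 / 3, 3), sides = 2)
    matrix(f[2:(n + 1), ], n, ncol(m))
  }
  t(smooth_dim1(t(smooth_dim1(mat))))
}

# Bilinear lookup of `m` at real-valued (R, C) coordinate arrays (1-based).
# Coordinates whose interpolation support falls outside the raster yield
# `fill`. R and C must have identical length; result has that length.
sample_bilinear <- function(m, R, C, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  r0 <- floor(R); c0 <- floor(C)
  fr <- R - r0; fc <- C - c0
  corner <- function(ri, ci, w) {
    v <- rep(NA_real_, length(ri))
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    out <- w * v
    out[w == 0] <- 0
    out
  }
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc);       w11 <- fr * fc
  out <- corner(r0, c0, w00) + corner(r0, c0 + 1L, w01) +
    corner(r0 + 1L, c0, w10) + corner(r0 + 1L, c0 + 1L, w11)
  out[is.na(out)] <- fill
  out
}

# Shift image content so out[i, j] = m[i + dy, j + dx] (bilinear for
# fractional shifts, exact gather for integer ones); outside -> fill.
translate_pixels <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(fill, H, W)
    src_r <- seq_len(H) + as.integer(round(dy))
    src_c <- seq_len(W) + as.integer(round(dx))
    ok_r <- src_r >= 1 & src_r <= H
    ok_c <- src_c >= 1 & src_c <= W
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    return(out)
  }
  R <- matrix(seq_len(H) + dy, H, W)
  C <- matrix(rep(seq_len(W) + dx, each = H), H, W)
  matrix(sample_bilinear(m, as.numeric(R), as.numeric(C), fill = fill), H, W)
}

# Abbreviated content hash for provenance records: md5 of a file, or of the
# serialized JSON of an R object written to a temporary file.
content_hash <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(unname(tools::md5sum(x)))
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
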