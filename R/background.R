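# Diffuse-background removal. The rolling-ball background is the upper
# envelope of a ball of radius r rolled under the intensity surface --
# equivalently the grayscale opening of the image with the ball cap as a
# non-flat structuring element. Autofluorescence is removed by scaled
# subtraction of a dedicated autofluorescence acquisition.

#' Ball structuring element
#'
#' The ball cap height profile `z(x, y) = sqrt(r^2 - x^2 - y^2)` over the
#' disk of radius `r`, as offset/height vectors for the morphology kernels.
#'
#' @param radius_px Ball radius in pixels (integer >= 1).
#' @return A `BallElement`: list with integer offsets `di`, `dj` and
#'   heights `z` (max `radius_px` at the centre).
#' @export
ball_element <- function(radius_px) {
  stopifnot(radius_px >= 1, radius_px == floor(radius_px))
  r <- as.integer(radius_px)
  off <- expand.grid(di = -r:r, dj = -r:r)
  keep <- off$di^2 + off$dj^2 <= r^2
  off <- off[keep, ]
  structure(list(di = as.integer(off$di), dj = as.integer(off$dj),
                 z = sqrt(r^2 - off$di^2 - off$dj^2),
                 radius_px = r),
            class = "BallElement")
}

# Grayscale opening with the ball: erode then dilate.
ball_opening <- function(px, ball) {
  er <- ball_erode(px, ball$di, ball$dj, ball$z)
  ball_dilate(er, ball$di, ball$dj, ball$z)
}

#' Rolling-ball background estimation
#'
#' Computes the diffuse background as the grayscale opening of the plane
#' with a ball of the given radius (erosion by the ball cap followed by
#' dilation); the result is everywhere `<=` the input. The radius must
#' exceed the largest foreground object so real signal is not absorbed into
#' the background.
#'
#' For radii above 16 px, `method = "auto"` follows the classical strategy
#' of rolling on a copy downscaled by `ceiling(radius / 16)` (block
#' minimum), upsampling the small background bilinearly, and clipping it
#' under the plane; `method = "exact"` always runs at full resolution.
#'
#' @param plane An `ImagePlane` or matrix.
#' @param radius_px Ball radius in pixels; default 50.
#' @param method `"auto"` (downscale when `radius_px > 16`), `"exact"`, or
#'   `"downscale"`.
#' @return Background `ImagePlane` (pointwise `<=` the input).
#' @export
rolling_ball_background <- function(plane, radius_px = 50,
                                    method = c("auto", "exact", "downscale")) {
  method <- match.arg(method)
  p <- as_image_plane(plane)
  px <- p$pixels
  use_downscale <- switch(method,
                          auto = radius_px > 16,
                          exact = FALSE,
                          downscale = TRUE)
  if (!use_downscale) {
    bg <- ball_opening(px, ball_element(radius_px))
  } else {
    s <- max(1L, as.integer(ceiling(radius_px / 16)))
    H <- nrow(px); W <- ncol(px)
    Hs <- ceiling(H / s); Ws <- ceiling(W / s)
    # block-minimum shrink; edge blocks replicate the last row/column
    ridx <- pmin(rep(seq_len(Hs * s)), H)
    cidx <- pmin(rep(seq_len(Ws * s)), W)
    padded <- px[ridx, cidx]
    small <- matrix(Inf, Hs, Ws)
    for (a in seq_len(s)) {
      for (b in seq_len(s)) {
        small <- pmin(small, padded[seq(a, by = s, length.out = Hs),
                                    seq(b, by = s, length.out = Ws)])
      }
    }
    r_small <- max(1L, as.integer(round(radius_px / s)))
    bg_small <- ball_opening(small, ball_element(r_small))
    # bilinear expansion: full-res pixel i maps to block coordinate
    # (i - 0.5)/s + 0.5 (block centres), clamped to the small raster
    rr <- pmin(pmax((seq_len(H) - 0.5) / s + 0.5, 1), Hs)
    cc <- pmin(pmax((seq_len(W) - 0.5) / s + 0.5, 1), Ws)
    Rg <- matrix(rr, H, W)
    Cg <- matrix(rep(cc, each = H), H, W)
    bg <- matrix(sample_bilinear(bg_small, as.numeric(Rg), as.numeric(Cg)),
                 H, W)
    bg <- pmin(bg, px)
  }
  image_plane(clip_u16(pmin(bg, px)), pixel_size = p$pixel_size)
}

#' Subtract the rolling-ball background
#'
#' `plane - rolling_ball_background(plane, radius_px)`, floored at 0.
#'
#' @inheritParams rolling_ball_background
#' @return Background-subtracted `ImagePlane` (pointwise `<=` the input).
#' @export
subtract_background <- function(plane, radius_px = 50,
                                method = c("auto", "exact", "downscale")) {
  p <- as_image_plane(plane)
  bg <- rolling_ball_background(p, radius_px, method = method)
  out <- p$pixels - bg$pixels
  out[out < 0] <- 0
  image_plane(clip_u16(out), pixel_size = p$pixel_size)
}

#' Subtract an autofluorescence acquisition from a marker channel
#'
#' Endogenous tissue/debris autofluorescence recorded as its own channel is
#' removed from a marker channel by scaled subtraction, floored at 0. With
#' `scale = "auto"` the scale is the least-squares slope of the marker on
#' the autofluorescence image restricted to signal-poor pixels (marker below
#' its median), clipped to `[0, 3]`; this estimates how strongly the shared
#' autofluorescence component leaks into the marker exposure without being
#' biased by true staining.
#'
#' @param marker,af Same-shaped `ImagePlane`s or matrices.
#' @param scale Nonnegative number, or `"auto"` (default).
#' @return Corrected `ImagePlane`; attribute `"scale"` records the scale
#'   used.
#' @export
subtract_autofluorescence <- function(marker, af, scale = "auto") {
  mp <- as_image_plane(marker)
  ap <- as_image_plane(af)
  if (!identical(dim(mp$pixels), dim(ap$pixels))) {
    stop("marker and autofluorescence shapes differ")
  }
  m <- mp$pixels; a <- ap$pixels
  if (identical(scale, "auto")) {
    lo <- m < stats::quantile(m, 0.5, names = FALSE)
    if (sum(lo) >= 2 && stats::var(a[lo]) > 0) {
      fit <- stats::cov(a[lo], m[lo]) / stats::var(a[lo])
    } else {
      fit <- 0
    }
    scale <- min(max(fit, 0), 3)
  }
  stopifnot(is.numeric(scale), length(scale) == 1, scale >= 0)
  out <- m - scale * a
  out[out < 0] <- 0
  res <- image_plane(clip_u16(out), pixel_size = mp$pixel_size)
  attr(res, "scale") <- scale
  res
}
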