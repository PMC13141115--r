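#' Build a shading (flat-field) correction field from a reference image
#'
#' Fluorescence tiles suffer a smooth multiplicative illumination
#' inhomogeneity (vignetting); dividing by a normalized reference field
#' removes it. The reference -- typically an image of a uniform fluorescent
#' target -- is floored at its `floor_quantile` intensity (so dark or dead
#' pixels cannot explode the division) and normalized to mean 1.
#'
#' @param reference An `ImagePlane` (or matrix) of the shading reference.
#' @param floor_quantile Quantile in `(0, 0.5)` used as the intensity floor;
#'   default 0.01.
#' @return A `ShadingField`: list with `field` (positive matrix, mean 1) and
#'   `source`.
#' @seealso [correct_shading()]
#' @export
build_shading_field <- function(reference, floor_quantile = 0.01) {
  px <- plane_pixels(reference)
  stopifnot(floor_quantile > 0, floor_quantile < 0.5)
  if (all(px == 0)) stop("degenerate shading reference: all pixels zero")
  q <- stats::quantile(px, floor_quantile, names = FALSE)
  # a reference with many dead pixels can put the quantile at zero; the
  # floor must stay positive for the division to be defined everywhere
  q <- max(q, min(px[px > 0]))
  floored <- pmax(px, q)
  field <- floored / mean(floored)
  if (min(field) <= 0) stop("degenerate shading reference: field not positive")
  structure(list(field = field, source = "reference_image"),
            class = "ShadingField")
}

#' @rdname build_shading_field
#' @param shape Integer `(height, width)` for a unit (no-op) field.
#' @export
uniform_shading_field <- function(shape) {
  structure(list(field = matrix(1, shape[1], shape[2]), source = "uniform"),
            class = "ShadingField")
}

#' @export
print.ShadingField <- function(x, ...) {
  cat(sprintf("<ShadingField %d x %d (%s), range [%.3f, %.3f]>\n",
              nrow(x$field), ncol(x$field), x$source,
              min(x$field), max(x$field)))
  invisible(x)
}

#' Apply shading correction to a tile
#'
#' Divides the tile by the normalized shading field, rounds half-up and
#' clips to the 16-bit range. With the field that produced the tile this is
#' the exact inverse of multiplicative shading, up to rounding.
#'
#' @param tile An `ImagePlane` or matrix.
#' @param field A `ShadingField` of the same shape.
#' @return Corrected `ImagePlane`.
#' @export
correct_shading <- function(tile, field) {
  stopifnot(inherits(field, "ShadingField"))
  p <- as_image_plane(tile)
  if (!identical(dim(p$pixels), dim(field$field))) {
    stop(sprintf("tile shape (%d,%d) does not match shading field (%d,%d)",
                 nrow(p$pixels), ncol(p$pixels),
                 nrow(field$field), ncol(field$field)))
  }
  image_plane(clip_u16(p$pixels / field$field), pixel_size = p$pixel_size)
}

#' Flatten a brightfield image by Gaussian division
#'
#' Brightfield snapshots carry a slowly varying illumination gradient.
#' Dividing the image by a heavily Gaussian-smoothed copy of itself
#' (reflective boundaries) and rescaling by the global mean removes the
#' gradient while preserving local texture and overall brightness.
#'
#' @param image An `ImagePlane` or matrix.
#' @param sigma_px Gaussian standard deviation in pixels (>= 1); default 50,
#'   well above cellular texture scales.
#' @return Flattened `ImagePlane`.
#' @export
brightfield_flatten <- function(image, sigma_px = 50) {
  stopifnot(sigma_px >= 1)
  p <- as_image_plane(image)
  px <- p$pixels
  if (all(px == 0)) stop("degenerate input: all pixels zero")
  sm <- gaussian_smooth(px, sigma_px)
  out <- px
  nz <- sm > 0
  out[nz] <- px[nz] / sm[nz] * mean(px)
  out[!nz] <- 0
  image_plane(clip_u16(out), pixel_size = p$pixel_size)
}

#' Collapse a z-stack by orthogonal projection
#'
#' For chip samples imaged as focal series, the stack is collapsed to one
#' plane. `mode = "mean"` is the per-pixel arithmetic mean over z.
#' `mode = "weighted_contrast"` weights each slice per pixel by its local
#' contrast (3x3-window variance plus a small epsilon), normalized per
#' pixel, so in-focus structure dominates the projection.
#'
#' @param stack A [z_stack()].
#' @param mode `"weighted_contrast"` (default) or `"mean"`.
#' @param epsilon Weight floor avoiding a zero total weight; default 1e-6.
#' @return Projected `ImagePlane`.
#' @export
project_weighted <- function(stack, mode = c("weighted_contrast", "mean"),
                             epsilon = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "ZStack"), length(stack$slices) >= 1)
  mats <- lapply(stack$slices, function(s) s$pixels)
  if (mode == "mean" || length(mats) == 1) {
    out <- Reduce(`+`, mats) / length(mats)
  } else {
    num <- 0; den <- 0
    for (m in mats) {
      v <- box_mean3(m * m) - box_mean3(m)^2
      v[v < 0] <- 0
      w <- epsilon + v
      num <- num + w * m
      den <- den + w
    }
    out <- num / den
  }
  image_plane(clip_u16(out), pixel_size = stack$slices[[1]]$pixel_size)
}
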