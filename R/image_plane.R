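#' Single-plane 16-bit image
#'
#' An `ImagePlane` is the atom of the pipeline: a 2-D raster of unsigned
#' 16-bit intensities with optional physical pixel size. Pixels follow the
#' (row, col) convention with the origin at the top-left.
#'
#' @param pixels Numeric or integer matrix with values in `[0, 65535]`.
#' @param pixel_size Optional micrometres per pixel (positive scalar).
#' @return An `ImagePlane` object (list with `pixels` and `pixel_size`).
#' @examples
#' p <- image_plane(matrix(0:3, 2, 2))
#' dim(p)
#' @export
image_plane <- function(pixels, pixel_size = NULL) {
  if (inherits(pixels, "ImagePlane")) {
    if (is.null(pixel_size)) pixel_size <- pixels$pixel_size
    pixels <- pixels$pixels
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop("image must have height >= 1 and width >= 1")
  }
  if (anyNA(pixels)) stop("pixels contain NA")
  if (any(pixels < 0) || any(pixels > U16_MAX)) {
    stop("intensities must lie in [0, 65535]")
  }
  if (any(pixels != floor(pixels))) {
    stop("intensities must be integral; round or clip first")
  }
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0)
  }
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "ImagePlane")
}

#' @export
dim.ImagePlane <- function(x) dim(x$pixels)

#' @export
print.ImagePlane <- function(x, ...) {
  cat(sprintf("<ImagePlane %d x %d, range [%d, %d]%s>\n",
              nrow(x$pixels), ncol(x$pixels),
              as.integer(min(x$pixels)), as.integer(max(x$pixels)),
              if (is.null(x$pixel_size)) ""
              else sprintf(", %.3g um/px", x$pixel_size)))
  invisible(x)
}

#' Test or coerce to ImagePlane
#'
#' `as_image_plane()` accepts an `ImagePlane` (returned unchanged) or a bare
#' matrix, which is validated and wrapped.
#'
#' @param x Object to test or coerce.
#' @return `is_image_plane()`: logical. `as_image_plane()`: an `ImagePlane`.
#' @export
is_image_plane <- function(x) inherits(x, "ImagePlane")

#' @rdname is_image_plane
#' @export
as_image_plane <- function(x) {
  if (is_image_plane(x)) x else image_plane(x)
}

# Extract the pixel matrix from an ImagePlane or bare matrix.
plane_pixels <- function(x) {
  if (is_image_plane(x)) x$pixels else as_image_plane(x)$pixels
}

#' Z-stack of image planes
#'
#' An ordered list of same-shaped [image_plane()] slices, e.g. the focal
#' series acquired on a porous-membrane chip, plus an optional slice spacing.
#'
#' @param slices List of `ImagePlane` (or matrices) of identical shape.
#' @param z_spacing Optional micrometres between slices (positive scalar).
#' @return A `ZStack` object.
#' @seealso [project_weighted()]
#' @export
z_stack <- function(slices, z_spacing = NULL) {
  if (length(slices) < 1) stop("a z-stack needs at least one slice")
  slices <- lapply(slices, as_image_plane)
  shapes <- vapply(slices, function(p) dim(p$pixels), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("all z-stack slices must share one shape")
  }
  if (!is.null(z_spacing)) {
    stopifnot(is.numeric(z_spacing), length(z_spacing) == 1, z_spacing > 0)
  }
  structure(list(slices = slices, z_spacing = z_spacing), class = "ZStack")
}

#' @export
print.ZStack <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("<ZStack %d slices of %d x %d>\n", length(x$slices), d[1], d[2]))
  invisible(x)
}

#' Tile-grid geometry of an acquisition
#'
#' Describes how a tile scan covers the sample: grid dimensions, fractional
#' overlap between adjacent tiles, the stage traversal order, and the common
#' tile shape.
#'
#' @param rows,cols Positive integers; grid dimensions.
#' @param overlap_fraction Fraction of tile extent shared by adjacent tiles,
#'   in `[0, 0.5)`.
#' @param acquisition_order `"row_major"` (every row left to right) or
#'   `"snake_by_row"` (odd rows left to right, even rows right to left).
#' @param tile_shape Integer `(height, width)` of every tile, in pixels.
#' @return A `TileGrid` object.
#' @export
tile_grid <- function(rows, cols, overlap_fraction = 0.1,
                      acquisition_order = c("row_major", "snake_by_row"),
                      tile_shape) {
  acquisition_order <- match.arg(acquisition_order)
  stopifnot(rows >= 1, cols >= 1, rows == floor(rows), cols == floor(cols))
  if (overlap_fraction < 0 || overlap_fraction >= 0.5) {
    stop("overlap_fraction must lie in [0, 0.5)")
  }
  stopifnot(length(tile_shape) == 2, all(tile_shape >= 1))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 overlap_fraction = overlap_fraction,
                 acquisition_order = acquisition_order,
                 tile_shape = as.integer(tile_shape)),
            class = "TileGrid")
}

#' @export
print.TileGrid <- function(x, ...) {
  cat(sprintf("<TileGrid %d x %d, tiles %d x %d, overlap %.0f%%, %s>\n",
              x$rows, x$cols, x$tile_shape[1], x$tile_shape[2],
              100 * x$overlap_fraction, x$acquisition_order))
  invisible(x)
}

# Map acquisition index -> (grid_row, grid_col), 0-based, honouring snake
# traversal. Returns a data.frame in acquisition order.
grid_cells <- function(grid) {
  cells <- expand.grid(grid_col = seq_len(grid$cols) - 1L,
                       grid_row = seq_len(grid$rows) - 1L)[, 2:1]
  if (grid$acquisition_order == "snake_by_row") {
    for (r in seq_len(grid$rows) - 1L) {
      if (r %% 2 == 1) {
        idx <- which(cells$grid_row == r)
        cells$grid_col[idx] <- rev(cells$grid_col[idx])
      }
    }
  }
  cells$tile <- seq_len(nrow(cells))
  cells
}
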