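#' Read and write single image planes as TIFF
#'
#' `read_plane()` reads a single-plane grayscale TIFF into an
#' [image_plane()]. 8-bit files are promoted to the 16-bit scale by
#' multiplying with 257 (so 255 maps to 65535); 16-bit files are read
#' verbatim. Multi-page or RGB files are rejected with an informative error.
#' `write_plane()` writes uncompressed 16-bit grayscale TIFF; the pair
#' round-trips losslessly.
#'
#' @param path TIFF file path.
#' @param pixel_size Optional micrometres per pixel to attach on read.
#' @return `read_plane()`: an `ImagePlane`. `write_plane()`: `path`,
#'   invisibly.
#' @export
read_plane <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) != 1) {
    stop(sprintf("expected a single-plane TIFF, got pages=%d: %s",
                 length(pages), path))
  }
  px <- pages[[1]]
  if (length(dim(px)) == 3) {
    stop(sprintf("expected grayscale, got %d samples per pixel (channel axis): %s",
                 dim(px)[3], path))
  }
  bits <- attr(px, "bits.per.sample")
  if (!is.null(bits) && bits == 8) px <- px * 257
  attributes(px) <- list(dim = dim(px))
  image_plane(px, pixel_size = pixel_size)
}

#' @rdname read_plane
#' @param plane An `ImagePlane` or matrix of intensities in `[0, 65535]`.
#' @export
write_plane <- function(plane, path) {
  px <- plane_pixels(plane)
  ok <- tryCatch(tiff::writeTIFF(px / U16_MAX, path, bits.per.sample = 16L,
                                 compression = "none"),
                 error = function(e) stop("cannot write TIFF: ", path,
                                          " (", conditionMessage(e), ")"))
  invisible(path)
}

#' Read a multi-page TIFF as a z-stack
#'
#' @param path Multi-page grayscale TIFF.
#' @param z_spacing Optional slice spacing in micrometres.
#' @return A [z_stack()].
#' @export
read_zstack <- function(path, z_spacing = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  slices <- lapply(pages, function(px) {
    if (length(dim(px)) == 3) stop("z-stack pages must be grayscale: ", path)
    bits <- attr(px, "bits.per.sample")
    if (!is.null(bits) && bits == 8) px <- px * 257
    attributes(px) <- list(dim = dim(px))
    image_plane(px)
  })
  z_stack(slices, z_spacing = z_spacing)
}

#' Assemble per-cycle plane stacks into a hyperstack
#'
#' Planes acquired on the same day (cycle) are combined into a stack, and
#' consecutive cycles are concatenated into one hyperstack whose page order
#' is cycle-major, then manifest row order within the cycle. The result is
#' unregistered; see [register_cycles()].
#'
#' @param per_cycle_stacks A list with one element per cycle, each a
#'   `list(cycle = <int>, planes = <list of ImagePlane>)`; planes must be in
#'   the manifest row order of that cycle.
#' @param manifest Validated manifest data.frame (see [read_manifest()]).
#' @return A `HyperStack`: list with `planes`, `records`, `registered`.
#' @export
assemble_hyperstack <- function(per_cycle_stacks, manifest) {
  manifest <- validate_manifest(manifest)
  cycles <- vapply(per_cycle_stacks, function(s) as.integer(s$cycle), 1L)
  if (anyDuplicated(cycles)) stop("duplicate cycle in per_cycle_stacks")
  per_cycle_stacks <- per_cycle_stacks[order(cycles)]
  cycles <- sort(cycles)
  if (!setequal(cycles, unique(manifest$cycle))) {
    stop("cycles supplied (", paste(cycles, collapse = ","),
         ") do not match manifest cycles (",
         paste(sort(unique(manifest$cycle)), collapse = ","), ")")
  }
  planes <- list()
  records <- manifest[0, ]
  ref_shape <- NULL
  for (s in per_cycle_stacks) {
    rows <- which(manifest$cycle == s$cycle)
    if (length(s$planes) != length(rows)) {
      stop(sprintf("cycle %d: %d planes supplied but manifest lists %d channels",
                   s$cycle, length(s$planes), length(rows)))
    }
    for (k in seq_along(rows)) {
      p <- as_image_plane(s$planes[[k]])
      if (is.null(ref_shape)) ref_shape <- dim(p$pixels)
      if (!identical(dim(p$pixels), ref_shape)) {
        stop(sprintf("cycle %d / %s: shape (%d,%d) != (%d,%d)",
                     s$cycle, manifest$channel_name[rows[k]],
                     nrow(p$pixels), ncol(p$pixels),
                     ref_shape[1], ref_shape[2]))
      }
      planes[[length(planes) + 1L]] <- p
      records <- rbind(records, manifest[rows[k], ])
    }
  }
  rownames(records) <- NULL
  structure(list(planes = planes, records = records, registered = FALSE),
            class = "HyperStack")
}

#' @export
print.HyperStack <- function(x, ...) {
  d <- dim(x$planes[[1]]$pixels)
  cat(sprintf("<HyperStack %d planes (%d cycles) of %d x %d, %s>\n",
              length(x$planes), length(unique(x$records$cycle)), d[1], d[2],
              if (isTRUE(x$registered)) "registered" else "unregistered"))
  invisible(x)
}

#' Page names of a hyperstack
#'
#' Pages are named `c{cycle}_{marker}`, e.g. `c1_DAPI`, `c2_LYVE-1`.
#'
#' @param stack A `HyperStack`.
#' @return Character vector, one name per plane.
#' @export
hyperstack_page_names <- function(stack) {
  sprintf("c%d_%s", stack$records$cycle, stack$records$marker)
}

#' Write and read a hyperstack container
#'
#' The on-disk container is an uncompressed multi-page 16-bit TIFF in page
#' order (cycle, manifest row), plus a JSON sidecar `<path>.json` carrying
#' the channel records, the page names and the registration flag. The pair
#' round-trips planes bit-exactly and records field-exactly.
#'
#' @param stack A `HyperStack`.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `write_hyperstack()`: `path`, invisibly. `read_hyperstack()`: a
#'   `HyperStack`.
#' @export
write_hyperstack <- function(stack, path) {
  stopifnot(inherits(stack, "HyperStack"))
  mats <- lapply(stack$planes, function(p) p$pixels / U16_MAX)
  ok <- tryCatch(tiff::writeTIFF(mats, path, bits.per.sample = 16L,
                                 compression = "none"),
                 error = function(e) stop("cannot write hyperstack: ", path,
                                          " (", conditionMessage(e), ")"))
  sidecar <- list(page_names = hyperstack_page_names(stack),
                  records = stack$records,
                  registered = isTRUE(stack$registered),
                  pixel_size = stack$planes[[1]]$pixel_size)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_hyperstack
#' @export
read_hyperstack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such hyperstack: ", path)
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  records <- validate_manifest(as.data.frame(meta$records))
  pixel_size <- if (is.null(meta$pixel_size)) NULL else meta$pixel_size
  planes <- lapply(pages, function(px) {
    attributes(px) <- list(dim = dim(px))
    image_plane(px, pixel_size = pixel_size)
  })
  if (length(planes) != nrow(records)) {
    stop("hyperstack page count disagrees with sidecar records")
  }
  structure(list(planes = planes, records = records,
                 registered = isTRUE(meta$registered)),
            class = "HyperStack")
}
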