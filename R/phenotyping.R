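# Imaging cytometry: segment nuclei on the nuclear channel, binarize marker
# channels, measure per-cell marker overlap fractions and intensities, and
# assign identities by the >= 60 % nuclear-overlap rule. Two adjacent cells
# (e.g. a LYVE-1+ endothelial cell hugging an IBA1+ macrophage) share
# membrane signal in projection; requiring the nucleus itself to be mostly
# covered by a marker's mask avoids calling spurious biphenotypic cells.

# Otsu's threshold on the 16-bit scale (EBImage backend).
otsu_threshold <- function(px) {
  if (stats::var(as.numeric(px)) == 0) {
    stop("degenerate input: constant plane has no threshold")
  }
  th <- EBImage::otsu(EBImage::Image(px / U16_MAX), range = c(0, 1),
                      levels = 65536L)
  th * U16_MAX
}

#' Segment nuclei from the nuclear channel
#'
#' Classical pipeline: Gaussian smoothing, Otsu global threshold, hole
#' filling, then a watershed split of touching nuclei on the negated
#' distance transform (seeded at regional maxima with minimum separation
#' `ceiling(sqrt(min_area))` pixels). Components outside
#' `[min_area, max_area]` are discarded and labels are made contiguous.
#'
#' @param nuclear `ImagePlane` or matrix of the nuclear (DAPI) channel.
#' @param smooth_sigma Gaussian sigma in pixels; default 1.5.
#' @param min_area,max_area Area bounds in px^2; defaults 30 and 2000.
#'   `min_area` also sets the watershed seed window: maxima closer than
#'   about `sqrt(min_area)` px (the diameter of the smallest admissible
#'   nucleus) cannot both seed, so the seed-suppression radius is half
#'   that.
#' @param seed_tolerance Watershed merge tolerance in distance-map units;
#'   peaks shallower than this against their saddle are merged. Default
#'   0.5.
#' @return A `LabelMap`: integer matrix, 0 = background, 1..N = nuclei,
#'   with attribute `n_cells`.
#' @export
segment_nuclei <- function(nuclear, smooth_sigma = 1.5, min_area = 30,
                           max_area = 2000, seed_tolerance = 0.5) {
  px <- plane_pixels(nuclear)
  if (stats::var(as.numeric(px)) == 0) {
    stop("degenerate input: constant nuclear plane")
  }
  sm <- gaussian_smooth(px, smooth_sigma)
  mask <- sm >= otsu_threshold(clip_u16(sm))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = seed_tolerance,
                               ext = max(1L, ceiling(sqrt(min_area) / 2)))
  labels <- as.matrix(EBImage::imageData(labels))
  relabel_filtered(labels, min_area, max_area)
}

# Drop labels outside the area bounds and relabel contiguously (by
# ascending original label).
relabel_filtered <- function(labels, min_area = 1, max_area = Inf) {
  storage.mode(labels) <- "integer"
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  lut <- integer(length(areas) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  out <- matrix(lut[labels + 1L], nrow(labels), ncol(labels))
  attr(out, "n_cells") <- length(keep)
  class(out) <- c("LabelMap", class(out))
  out
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("<LabelMap %d x %d, %d cells>\n", nrow(x), ncol(x),
              attr(x, "n_cells")))
  invisible(x)
}

#' Export / import a label map as 16-bit integer TIFF
#'
#' The import path admits label maps produced by external nucleus
#' segmenters (e.g. deep-learning tools) exported as integer TIFF; labels
#' are made contiguous on read.
#'
#' @param labels A `LabelMap` or integer matrix.
#' @param path TIFF path.
#' @param expected_shape Optional `(height, width)` the imported map must
#'   match.
#' @return `import_labelmap()`: a `LabelMap`. `export_labelmap()`: `path`,
#'   invisibly.
#' @export
import_labelmap <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop("no such label map: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) != 1) stop("label map must be a single-plane TIFF")
  lab <- pages[[1]]
  if (length(dim(lab)) == 3) stop("label map must be single-channel")
  fmt <- attr(lab, "sample.format")
  bits <- attr(lab, "bits.per.sample")
  if (identical(fmt, "float") || (!is.null(bits) && bits > 16)) {
    stop("label map has non-integer content (float-valued or >16-bit file)")
  }
  attributes(lab) <- list(dim = dim(lab))
  if (any(lab != floor(lab))) {
    stop("label map has non-integer content")
  }
  if (any(lab < 0)) stop("label map contains negative labels")
  if (!is.null(expected_shape) &&
      !identical(as.integer(dim(lab)), as.integer(expected_shape))) {
    stop(sprintf("label map shape (%d,%d) does not match expected (%d,%d)",
                 nrow(lab), ncol(lab), expected_shape[1], expected_shape[2]))
  }
  # relabel {0, 3, 7} -> {0, 1, 2} preserving regions
  u <- sort(unique(as.integer(lab[lab > 0])))
  lut <- integer(max(c(0L, u)) + 1L)
  lut[u + 1L] <- seq_along(u)
  storage.mode(lab) <- "integer"
  out <- matrix(lut[lab + 1L], nrow(lab), ncol(lab))
  attr(out, "n_cells") <- length(u)
  class(out) <- c("LabelMap", class(out))
  out
}

#' @rdname import_labelmap
#' @export
export_labelmap <- function(labels, path) {
  lab <- unclass(labels)
  attributes(lab) <- list(dim = dim(lab))
  if (max(lab) > U16_MAX) stop("more than 65535 labels; cannot write 16-bit")
  tiff::writeTIFF(lab / U16_MAX, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Binarize a marker channel
#'
#' `mask = plane >= threshold`, with the threshold from Otsu's criterion or
#' supplied fixed. Cytoplasmic and membrane markers vary widely in dynamic
#' range, so a per-channel fixed threshold is supported.
#'
#' @param plane `ImagePlane` or matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity for `method = "fixed"`.
#' @return Logical matrix; attribute `"threshold"` records the cut used.
#' @export
marker_mask <- function(plane, method = c("otsu", "fixed"),
                        fixed_threshold = NULL) {
  method <- match.arg(method)
  px <- plane_pixels(plane)
  th <- if (method == "otsu") {
    otsu_threshold(px)
  } else {
    stopifnot(is.numeric(fixed_threshold), length(fixed_threshold) == 1)
    fixed_threshold
  }
  mask <- px >= th
  attr(mask, "threshold") <- th
  mask
}

#' Per-cell marker overlap fractions
#'
#' For each cell, the fraction of its nuclear pixels lying inside the
#' binarized marker mask: `|cell & mask| / |cell|`.
#'
#' @param labels A `LabelMap`.
#' @param mask Logical matrix of the same shape.
#' @return Numeric vector of length `n_cells`, named by cell id.
#' @export
overlap_fractions <- function(labels, mask) {
  if (!identical(dim(labels), dim(mask))) {
    stop("label map and mask shapes differ")
  }
  n <- attr(labels, "n_cells") %||% max(labels)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  fg <- labels > 0
  areas <- tabulate(labels[fg], nbins = n)
  hits <- tabulate(labels[fg & mask], nbins = n)
  stats::setNames(hits / areas, as.character(seq_len(n)))
}

#' Assign cell identities from marker overlap fractions
#'
#' A marker qualifies for a cell when the nucleus is at least
#' `threshold` (default 60 %) covered by that marker's mask. No qualifying
#' marker leaves the cell `"unassigned"`; exactly one assigns it. With
#' several qualifying markers and `exclusive = TRUE` the largest fraction
#' wins, unless the top two differ by less than 0.01 -- a near-tie is
#' reported (`tie_flag`) and left `"unassigned"` rather than guessed, to
#' avoid manufacturing biphenotypic cells. With `exclusive = FALSE` all
#' qualifying markers are listed, joined by `";"`.
#'
#' @param fractions Numeric matrix or data.frame, cells x markers, of
#'   overlap fractions in `[0, 1]`; column names are the marker names.
#' @param threshold Qualifying overlap fraction in `(0, 1]`; default 0.60.
#' @param exclusive Resolve multi-marker conflicts by argmax (default).
#' @param tie_margin Near-tie width on the top two fractions; default 0.01.
#' @return `data.frame` with columns `assigned_identity` and `tie_flag`,
#'   one row per cell.
#' @export
assign_identity <- function(fractions, threshold = 0.60, exclusive = TRUE,
                            tie_margin = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  fractions <- as.matrix(fractions)
  markers <- colnames(fractions)
  if (is.null(markers)) stop("fractions must have marker column names")
  n <- nrow(fractions)
  identity <- rep("unassigned", n)
  tie <- rep(FALSE, n)
  for (i in seq_len(n)) {
    q <- which(fractions[i, ] >= threshold)
    if (length(q) == 1) {
      identity[i] <- markers[q]
    } else if (length(q) > 1) {
      if (exclusive) {
        f <- fractions[i, q]
        ord <- order(f, decreasing = TRUE)
        if (f[ord[1]] - f[ord[2]] < tie_margin) {
          tie[i] <- TRUE   # too close to call; report, don't guess
        } else {
          identity[i] <- markers[q[ord[1]]]
        }
      } else {
        identity[i] <- paste(markers[q], collapse = ";")
      }
    }
  }
  data.frame(assigned_identity = identity, tie_flag = tie)
}

#' Quantify a registered hyperstack into a cell table
#'
#' Produces one record per segmented cell: centroid, area, per-marker
#' overlap fraction and mean intensity over the cell's pixels, and the
#' assigned identity under the nuclear-overlap rule. Intensities of markers
#' incompatible with the assigned identity are recorded but flagged invalid
#' (`valid_<marker>`), since e.g. a hepatic macrophage's nominal LYVE-1
#' intensity is not a meaningful measurement.
#'
#' @param stack A registered `HyperStack`.
#' @param labels A `LabelMap` matching the stack's plane shape.
#' @param masks Named list of logical matrices, one per marker (see
#'   [marker_mask()]). Marker names must match manifest `marker` entries.
#' @param threshold,exclusive,tie_margin Passed to [assign_identity()].
#' @param sample_id Free-text provenance tag stored on the table.
#' @return A `CellTable`: `data.frame` with columns `cell_id`,
#'   `centroid_row`, `centroid_col`, `area_px`, then per marker
#'   `frac_<m>`, `mean_<m>`, `valid_<m>`, then `assigned_identity`,
#'   `tie_flag`. Attributes `sample_id` and `config_hash` carry provenance.
#' @export
quantify <- function(stack, labels, masks, threshold = 0.60,
                     exclusive = TRUE, tie_margin = 0.01,
                     sample_id = "sample") {
  stopifnot(inherits(stack, "HyperStack"))
  if (!isTRUE(stack$registered)) {
    stop("hyperstack is not registered; run register_cycles() first")
  }
  shape <- dim(stack$planes[[1]]$pixels)
  if (!identical(as.integer(dim(labels)), as.integer(shape))) {
    stop("label map shape does not match hyperstack planes")
  }
  markers <- names(masks)
  if (is.null(markers) || any(markers == "")) {
    stop("masks must be a named list keyed by marker")
  }
  n <- attr(labels, "n_cells") %||% max(labels)
  fg <- labels > 0
  lab_fg <- labels[fg]
  if (n > 0) {
    areas <- tabulate(lab_fg, nbins = n)
    rows <- row(labels)[fg]
    cols <- col(labels)[fg]
    centroid_r <- tabulate_sum(lab_fg, rows, n) / areas
    centroid_c <- tabulate_sum(lab_fg, cols, n) / areas
  } else {
    areas <- integer(0); centroid_r <- numeric(0); centroid_c <- numeric(0)
  }
  tab <- data.frame(cell_id = seq_len(n),
                    centroid_row = centroid_r,
                    centroid_col = centroid_c,
                    area_px = as.integer(areas))
  frac <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  for (m in markers) {
    if (!identical(dim(masks[[m]]), dim(labels))) {
      stop("mask for marker ", m, " has the wrong shape")
    }
    frac[, m] <- overlap_fractions(labels, masks[[m]])
    plane_i <- which(stack$records$marker == m &
                     stack$records$role == "marker")
    if (length(plane_i) < 1) {
      stop("marker ", m, " has no marker-role plane in the hyperstack")
    }
    px <- stack$planes[[plane_i[1]]]$pixels
    mean_int <- if (n > 0) tabulate_sum(lab_fg, px[fg], n) / areas
                else numeric(0)
    tab[[paste0("frac_", m)]] <- unname(frac[, m])
    tab[[paste0("mean_", m)]] <- mean_int
  }
  ident <- if (n > 0) {
    assign_identity(frac, threshold = threshold, exclusive = exclusive,
                    tie_margin = tie_margin)
  } else {
    data.frame(assigned_identity = character(0), tie_flag = logical(0))
  }
  for (m in markers) {
    tab[[paste0("valid_", m)]] <- ident$assigned_identity == m
  }
  tab$assigned_identity <- ident$assigned_identity
  tab$tie_flag <- ident$tie_flag
  cfg <- list(threshold = threshold, exclusive = exclusive,
              tie_margin = tie_margin, markers = markers)
  attr(tab, "sample_id") <- sample_id
  attr(tab, "config_hash") <- content_hash(cfg)
  class(tab) <- c("CellTable", "data.frame")
  tab
}

# Group sums of `values` by positive integer `groups` (1..n).
tabulate_sum <- function(groups, values, n) {
  rs <- rowsum(as.numeric(values), groups, reorder = TRUE)
  out <- numeric(n)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Write a cell table to CSV
#'
#' @param tab A `CellTable`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
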