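# Cross-cycle registration. Each staining cycle re-images the same section
# after coverslip removal and antibody stripping, so cycles drift by a small
# translation. The per-cycle nuclear (DAPI) channel is the reference: its
# shift against cycle 1 is estimated by phase correlation and applied to
# every channel of that cycle.

# Signed integer FFT frequencies for a dimension of size n.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k
}

# Phase correlation between two same-shaped matrices. Returns the integer
# peak (dy, dx) with wrap-around unfolding, optionally refined to 1/upsample
# pixel by a matrix-multiply DFT evaluated on a +-1.5 px neighbourhood of
# the integer peak. Convention: mov(x) = ref(x - s) yields s.
phase_corr_shift <- function(ref, mov, upsample = 1L) {
  H <- nrow(ref); W <- ncol(ref)
  F1 <- stats::fft(ref)
  F2 <- stats::fft(mov)
  Q <- Conj(F1) * F2
  mag <- Mod(Q)
  Q <- Q / pmax(mag, 1e-12)
  r <- Re(stats::fft(Q, inverse = TRUE)) / (H * W)
  peak <- arrayInd(which.max(r), dim(r))
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > H %/% 2) dy <- dy - H
  if (dx > W %/% 2) dx <- dx - W
  shift <- c(dy, dx)
  if (upsample > 1) {
    ky <- fft_freqs(H); kx <- fft_freqs(W)
    ys <- dy + seq(-1.5, 1.5, by = 1 / upsample)
    xs <- dx + seq(-1.5, 1.5, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(ys, ky) / H)
    Ex <- exp(2i * pi * outer(kx, xs) / W)
    C <- Re(Ey %*% Q %*% Ex)
    p <- arrayInd(which.max(C), dim(C))
    shift <- c(ys[p[1]], xs[p[2]])
  }
  shift
}

# Pearson correlation between ref and mov aligned at the (rounded) shift,
# computed on the exact-overlap region; returns 0 when degenerate.
aligned_correlation <- function(ref, mov, shift) {
  dy <- as.integer(round(shift[1])); dx <- as.integer(round(shift[2]))
  H <- nrow(ref); W <- ncol(ref)
  # mov[i, j] = ref[i - dy, j - dx]: compare ref[i-dy, j-dx] with mov[i, j]
  ri <- intersect(seq_len(H), seq_len(H) + dy)
  ci <- intersect(seq_len(W), seq_len(W) + dx)
  if (length(ri) < 2 || length(ci) < 2) return(0)
  a <- ref[ri - dy, ci - dx]
  b <- mov[ri, ci]
  if (stats::var(as.numeric(a)) == 0 || stats::var(as.numeric(b)) == 0) {
    return(0)
  }
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Estimate the rigid translation between two planes
#'
#' Phase cross-correlation: the translation is read off the peak of the
#' inverse FFT of the normalized cross-power spectrum, then refined to
#' `1/upsample` pixel by an upsampled DFT evaluated around the integer peak.
#' The returned shift `s = (dy, dx)` satisfies `moving(x) = reference(x - s)`
#' up to noise, so [apply_shift()] with `s` brings `moving` onto the
#' reference frame.
#'
#' @param reference,moving Same-shaped `ImagePlane`s or matrices; must not
#'   be constant.
#' @param upsample Subpixel refinement factor (integer >= 1); default 10.
#' @param max_shift Optional largest plausible shift magnitude per axis, in
#'   pixels. A larger estimate is treated as a registration failure: the
#'   shift is reported as `(0, 0)` with `flagged = TRUE`.
#' @return A `RigidShift`: list with `dy`, `dx`, `peak_correlation` (in
#'   `[0, 1]`), `flagged`, `cycle` (filled by [register_cycles()]).
#' @export
estimate_shift <- function(reference, moving, upsample = 10L,
                           max_shift = NULL) {
  ref <- plane_pixels(reference)
  mov <- plane_pixels(moving)
  if (!identical(dim(ref), dim(mov))) stop("plane shapes differ")
  if (stats::var(as.numeric(ref)) == 0 || stats::var(as.numeric(mov)) == 0) {
    stop("degenerate input: constant plane has no registration signal")
  }
  stopifnot(upsample >= 1)
  s <- phase_corr_shift(ref, mov, upsample = as.integer(upsample))
  corr <- max(0, aligned_correlation(ref, mov, s))
  flagged <- FALSE
  if (!is.null(max_shift) && (abs(s[1]) > max_shift || abs(s[2]) > max_shift)) {
    s <- c(0, 0)
    flagged <- TRUE
  }
  structure(list(dy = s[1], dx = s[2], peak_correlation = corr,
                 flagged = flagged, cycle = NA_integer_),
            class = "RigidShift")
}

#' @export
print.RigidShift <- function(x, ...) {
  cat(sprintf("<RigidShift dy=%.3f dx=%.3f corr=%.3f%s>\n", x$dy, x$dx,
              x$peak_correlation, if (isTRUE(x$flagged)) " FLAGGED" else ""))
  invisible(x)
}

#' Apply a rigid shift to a plane
#'
#' Resamples the plane by `(-dy, -dx)` so an image displaced by `(dy, dx)`
#' lands back on the reference frame. Integer shifts are exact pixel moves;
#' fractional shifts use bilinear interpolation. Borders the source does not
#' cover are set to `fill`.
#'
#' @param plane An `ImagePlane` or matrix.
#' @param shift A `RigidShift` or numeric `(dy, dx)`.
#' @param fill Fill intensity for uncovered borders; default 0.
#' @return Shifted `ImagePlane`.
#' @export
apply_shift <- function(plane, shift, fill = 0) {
  p <- as_image_plane(plane)
  if (inherits(shift, "RigidShift")) shift <- c(shift$dy, shift$dx)
  stopifnot(length(shift) == 2, all(is.finite(shift)))
  out <- translate_pixels(p$pixels, shift[1], shift[2], fill = fill)
  image_plane(clip_u16(out), pixel_size = p$pixel_size)
}

#' Register all cycles of a hyperstack on the nuclear reference
#'
#' The reference cycle (default the first) defines the fixed frame. For each
#' other cycle, the translation between the reference cycle's nuclear plane
#' and that cycle's nuclear plane is estimated with [estimate_shift()] and
#' applied identically to every plane of the cycle, so channels within a
#' cycle stay co-registered.
#'
#' @param stack An unregistered `HyperStack` (every cycle needs a `nuclear`
#'   manifest row).
#' @param reference_cycle Cycle id of the fixed frame; default the smallest.
#' @param upsample Subpixel factor passed to [estimate_shift()].
#' @param max_shift_frac Largest plausible shift as a fraction of the image
#'   extent (per axis); beyond it the cycle keeps its position and is
#'   flagged. Default 0.1.
#' @return List with `stack` (registered `HyperStack`) and `shifts` (one
#'   `RigidShift` per non-reference cycle).
#' @export
register_cycles <- function(stack, reference_cycle = NULL, upsample = 10L,
                            max_shift_frac = 0.1) {
  stopifnot(inherits(stack, "HyperStack"))
  cycles <- sort(unique(stack$records$cycle))
  if (is.null(reference_cycle)) reference_cycle <- cycles[1]
  if (!reference_cycle %in% cycles) stop("reference cycle not in stack")
  shape <- dim(stack$planes[[1]]$pixels)
  max_shift <- max_shift_frac * max(shape)
  ref_nuc <- stack$planes[[nuclear_row(stack$records, reference_cycle)]]
  shifts <- list()
  out <- stack
  for (cy in setdiff(cycles, reference_cycle)) {
    nuc <- stack$planes[[nuclear_row(stack$records, cy)]]
    s <- estimate_shift(ref_nuc, nuc, upsample = upsample,
                        max_shift = max_shift)
    s$cycle <- as.integer(cy)
    shifts[[length(shifts) + 1L]] <- s
    idx <- which(stack$records$cycle == cy)
    for (i in idx) out$planes[[i]] <- apply_shift(stack$planes[[i]], s)
  }
  out$registered <- TRUE
  list(stack = out, shifts = shifts)
}

#' Cross-cycle tissue-retention quality control on the nuclear channel
#'
#' Repeated antibody stripping can damage or detach tissue. After
#' registration, the nuclear planes of all cycles should coincide; this QC
#' binarizes each cycle's nuclear plane by Otsu's threshold and reports, per
#' cycle, the Dice coefficient against the reference cycle's nuclear mask
#' (`2|A&B| / (|A| + |B|)`) and the Pearson correlation of raw intensities
#' over the union support. Cycles whose Dice drops below `threshold_dice`
#' are flagged as possible tissue loss.
#'
#' @param stack A registered `HyperStack`.
#' @param threshold_dice Flagging threshold on Dice; default 0.7. Reported,
#'   never enforced.
#' @param reference_cycle Cycle compared against; default the smallest.
#' @return A `data.frame` with columns `cycle`, `dice`, `pearson`,
#'   `flagged`; the reference row has `dice = 1`, `pearson = 1`.
#' @export
dapi_retention_qc <- function(stack, threshold_dice = 0.7,
                              reference_cycle = NULL) {
  stopifnot(inherits(stack, "HyperStack"))
  if (!isTRUE(stack$registered)) {
    stop("hyperstack is not registered; run register_cycles() first")
  }
  cycles <- sort(unique(stack$records$cycle))
  if (is.null(reference_cycle)) reference_cycle <- cycles[1]
  ref <- stack$planes[[nuclear_row(stack$records, reference_cycle)]]$pixels
  ref_mask <- ref >= otsu_threshold(ref)
  rows <- lapply(cycles, function(cy) {
    if (cy == reference_cycle) {
      return(data.frame(cycle = cy, dice = 1, pearson = 1, flagged = FALSE))
    }
    cur <- stack$planes[[nuclear_row(stack$records, cy)]]$pixels
    cur_mask <- if (stats::var(as.numeric(cur)) == 0) {
      matrix(FALSE, nrow(cur), ncol(cur))
    } else {
      cur >= otsu_threshold(cur)
    }
    denom <- sum(ref_mask) + sum(cur_mask)
    dice <- if (denom == 0) 0 else 2 * sum(ref_mask & cur_mask) / denom
    union <- ref_mask | cur_mask
    pearson <- if (sum(union) >= 2 &&
                   stats::var(ref[union]) > 0 && stats::var(cur[union]) > 0) {
      stats::cor(ref[union], cur[union])
    } else {
      0
    }
    data.frame(cycle = cy, dice = dice, pearson = pearson,
               flagged = dice < threshold_dice)
  })
  do.call(rbind, rows)
}
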