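#' Correct the bidirectional scan-line mismatch
#'
#' Inverse of [apply_bidirectional_mismatch()]: translates every odd-indexed
#' y scan line back by `-shift_px` along x. Away from the x-borders
#' (`x` in `[|s|, nx - |s|)`), `correct(apply(stack, s), s)` restores the
#' original voxel values exactly; the `|s|` border columns of the shifted
#' lines are unrecoverable and take the fill value.
#'
#' @inheritParams apply_bidirectional_mismatch
#' @return object of the same type as `stack`.
#' @export
correct_bidirectional_mismatch <- function(stack, shift_px, fill = 0) {
  apply_bidirectional_mismatch(stack, -shift_px, fill = fill)
}

#' 3D median filter
#'
#' Per-voxel median over the `(2r+1)^3` neighborhood with edge replication;
#' the standard speckle-noise reduction step for confocal volumes. Idempotent
#' on constant images.
#'
#' @param stack a `channel_stack` or 3D numeric array.
#' @param radius_px neighborhood radius in voxels (>= 1).
#' @return object of the same type as `stack`.
#' @export
denoise_median <- function(stack, radius_px = 1L) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  a <- as_stack_array(stack)
  out <- array(cpp_median3d(as.numeric(a), dim(a), as.integer(radius_px)),
               dim = dim(a))
  if (inherits(stack, "channel_stack")) {
    stack$voxels <- out
    stack
  } else out
}

#' Otsu threshold of an integer intensity histogram
#'
#' Exhausts all candidate thresholds on the integer histogram and returns the
#' one maximizing the between-class variance. The returned threshold `t`
#' classifies intensities `> t` as foreground.
#'
#' @param values integer-valued intensities.
#' @param max_intensity top of the intensity range (e.g. `2^bit_depth - 1`).
#' @return the threshold, or `NA` if the histogram is degenerate (constant).
#' @keywords internal
otsu_threshold <- function(values, max_intensity) {
  counts <- as.numeric(tabulate(as.integer(values) + 1L,
                                nbins = max_intensity + 1L))
  n <- sum(counts)
  lev <- 0:max_intensity
  if (sum(counts > 0) < 2L) return(NA_real_)
  w0 <- cumsum(counts)                      # count with intensity <= t
  m0 <- cumsum(counts * lev)                # intensity sum with <= t
  mt <- m0[length(m0)]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / w0
  mu1 <- (mt - m0) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  # ties (a plateau of thresholds inducing the same partition) are broken by
  # the plateau midpoint, placing the cut between the two classes
  mean(lev[bcv == max(bcv)])
}

#' Binarize a channel by its intensity histogram
#'
#' Chooses a global threshold by Otsu's criterion (maximum between-class
#' variance over the full-depth integer histogram) and marks voxels strictly
#' above it as foreground. A constant image is not separable: the result is
#' an all-false mask with `degenerate = TRUE` in its provenance.
#'
#' @param stack a `channel_stack`.
#' @param threshold optional manual override; when given, Otsu's criterion is
#'   bypassed and voxels `> threshold` are foreground.
#' @return a `binary_mask`; provenance records the threshold, its source
#'   (`"otsu"` or `"manual"`) and the channel role.
#' @export
binarize_histogram <- function(stack, threshold = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  maxI <- 2^stack$bit_depth - 1
  degenerate <- FALSE
  if (is.null(threshold)) {
    threshold <- otsu_threshold(round(stack$voxels), maxI)
    source <- "otsu"
    if (is.na(threshold)) {
      degenerate <- TRUE
      threshold <- Inf
    }
  } else source <- "manual"
  binary_mask(stack$voxels > threshold,
              provenance = list(threshold = threshold,
                                threshold_source = source,
                                channel_role = stack$channel_role,
                                degenerate = degenerate))
}

#' Remove small connected components from a mask
#'
#' De-speckling: deletes every connected component (26-connectivity by
#' default) with fewer than `min_voxels` voxels. Idempotent.
#'
#' @param mask a `binary_mask` or logical array.
#' @param min_voxels minimum surviving component size in voxels (>= 1). The
#'   default 27 corresponds to a 3x3x3 blob.
#' @param connectivity 6, 18 or 26.
#' @return object of the same type as `mask`.
#' @export
despeckle <- function(mask, min_voxels = 27L, connectivity = 26L) {
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  a <- as_mask_array(mask)
  out <- a
  if (min_voxels > 1L && any(a)) {
    labels <- cpp_label3d(a, dim(a), as.integer(connectivity))
    n_lab <- attr(labels, "n_labels")
    sizes <- tabulate(labels, nbins = n_lab)
    small <- which(sizes < min_voxels)
    if (length(small))
      out <- array(a & !(labels %in% small), dim = dim(a))
  }
  if (inherits(mask, "binary_mask")) {
    mask$voxels <- out
    mask$provenance$despeckle_min_voxels <- min_voxels
    mask
  } else out
}

#' Standard conditioning chain for one channel
#'
#' Mismatch correction, 3D median filtering, histogram binarization and
#' de-speckling, in that order.
#'
#' @param stack a `channel_stack`.
#' @param shift_px bidirectional mismatch shift to undo (0 skips).
#' @param median_radius_px median filter radius (0 skips).
#' @param threshold optional manual threshold (default: Otsu).
#' @param min_voxels de-speckle minimum component size.
#' @param connectivity component connectivity for de-speckling.
#' @return a `binary_mask`.
#' @export
preprocess_channel <- function(stack, shift_px = 0L, median_radius_px = 1L,
                               threshold = NULL, min_voxels = 27L,
                               connectivity = 26L) {
  if (shift_px != 0L)
    stack <- correct_bidirectional_mismatch(stack, shift_px)
  if (median_radius_px >= 1L)
    stack <- denoise_median(stack, median_radius_px)
  mask <- binarize_histogram(stack, threshold = threshold)
  despeckle(mask, min_voxels = min_voxels, connectivity = connectivity)
}
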