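#' Region-based level-set outline of a cell in a brightfield plane
#'
#' Piecewise-constant (Chan--Vese-type) two-phase segmentation evolved from
#' an initial mask by discrete energy minimization: at each iteration the
#' inside/outside means `c1`, `c2` are recomputed and every boundary pixel is
#' flipped to the phase whose energy `(I - c)^2` plus `mu` times the
#' perimeter change is lower. Convergence is declared when fewer than 0.1%
#' of the mask's pixels change between iterations, or `n_iter` is reached.
#' When the two phases are indistinguishable (`|c1 - c2|` below `1e-6` of
#' the image range) there is no contrast to drive the contour and the
#' initial mask is returned with a degenerate flag.
#'
#' @param plane a 2D numeric matrix (a brightfield z-slice), or a
#'   `channel_stack` together with `z` selecting the slice.
#' @param init_mask 2D logical matrix, the non-empty initial contour
#'   interior.
#' @param n_iter maximum number of iterations (>= 1).
#' @param mu weight of the contour-length penalty, in squared-intensity
#'   units per boundary edge; 0 (default) disables smoothing, which is
#'   appropriate after median filtering.
#' @param z slice index when `plane` is a `channel_stack`.
#' @return 2D logical matrix with attributes `iterations`, `converged` and
#'   `degenerate`.
#' @export
segment_cell_levelset <- function(plane, init_mask, n_iter = 200L, mu = 0,
                                  z = NULL) {
  if (inherits(plane, "channel_stack")) {
    if (is.null(z)) stop("supply z to pick a brightfield slice")
    img <- plane$voxels[z, , ]
    dim(img) <- dim(plane$voxels)[2:3]
  } else img <- as.matrix(plane)
  mask <- init_mask
  if (!is.logical(mask) || !identical(dim(mask), dim(img)))
    stop("init_mask must be a logical matrix matching the plane")
  if (!any(mask)) stop("init_mask must be non-empty")
  if (n_iter < 1L) stop("n_iter must be >= 1")

  rng <- diff(range(img))
  iterations <- 0L
  converged <- FALSE
  degenerate <- FALSE
  ny <- nrow(img); nx <- ncol(img)
  pad <- function(m, fill) {
    out <- matrix(fill, ny + 2L, nx + 2L)
    out[2:(ny + 1L), 2:(nx + 1L)] <- m
    out
  }
  for (it in seq_len(n_iter)) {
    iterations <- it
    c1 <- mean(img[mask])
    c2 <- if (all(mask)) c1 else mean(img[!mask])
    if (abs(c1 - c2) < 1e-6 * max(rng, 1)) {
      degenerate <- TRUE
      break
    }
    mp <- pad(mask, FALSE)
    n_in <- mp[1:ny, 2:(nx + 1L)] + mp[3:(ny + 2L), 2:(nx + 1L)] +
            mp[2:(ny + 1L), 1:nx] + mp[2:(ny + 1L), 3:(nx + 2L)]
    boundary <- (mask & n_in < 4L) | (!mask & n_in > 0L)
    # energy change of flipping a pixel to the other phase; the perimeter of
    # a phase changes by (#same-phase neighbors - #other-phase neighbors)
    d_data <- ifelse(mask,
                     (img - c2)^2 - (img - c1)^2,
                     (img - c1)^2 - (img - c2)^2)
    n_same <- ifelse(mask, n_in, 4L - n_in)
    d_perim <- n_same - (4L - n_same)
    flip <- boundary & (d_data + mu * d_perim < 0)
    n_flip <- sum(flip)
    if (n_flip < 0.001 * max(sum(mask), 1)) {
      mask <- xor(mask, flip)
      converged <- TRUE
      break
    }
    mask <- xor(mask, flip)
    if (!any(mask)) break  # contour vanished
  }
  structure(mask, iterations = iterations, converged = converged || degenerate,
            degenerate = degenerate)
}

#' Extrude a 2D cell outline into a 3D mask bounded by the DAPI signal
#'
#' The brightfield outline gives the lateral cell boundary; the z-extent is
#' taken from the DAPI (nuclear) component that overlaps the outline in
#' projection. The outline is replicated over that component's contiguous
#' z-range. When no DAPI component overlaps the outline, the mask is empty
#' and flagged.
#'
#' @param outline2d 2D logical matrix (from [segment_cell_levelset()]).
#' @param dapi a 3D `binary_mask` (or logical array) of matching lateral
#'   shape.
#' @param connectivity component connectivity for the DAPI mask.
#' @return a `binary_mask` whose provenance records `z_range` and an
#'   `empty` flag.
#' @export
build_cell_mask_3d <- function(outline2d, dapi, connectivity = 26L) {
  a <- as_mask_array(dapi)
  d <- dim(a)
  if (!identical(dim(outline2d), d[2:3]))
    stop("outline2d lateral shape must match the DAPI mask")
  out <- array(FALSE, dim = d)
  labels <- cpp_label3d(a, d, as.integer(connectivity))
  n_lab <- attr(labels, "n_labels")
  if (n_lab > 0L) {
    # overlap of each component with the outline footprint
    foot <- aperm(array(outline2d, dim = d[c(2, 3, 1)]), c(3, 1, 2))
    ov <- tabulate(labels[foot], nbins = n_lab)
    best <- which.max(ov)
    if (ov[best] > 0L) {
      zs <- arrayInd(which(labels == best), d)[, 1]
      z0 <- min(zs); z1 <- max(zs)
      for (z in z0:z1) out[z, , ] <- outline2d
      return(binary_mask(out, provenance = list(z_range = c(z0, z1),
                                                empty = FALSE)))
    }
  }
  binary_mask(out, provenance = list(z_range = c(NA_integer_, NA_integer_),
                                     empty = TRUE))
}

#' Background region for noise-floor estimation
#'
#' Complement of the union of all supplied foreground masks, eroded so that
#' blur tails around objects do not contaminate the noise floor.
#'
#' @param masks list of `binary_mask` / logical arrays of identical shape.
#' @param erode_voxels number of 6-neighborhood erosion passes applied to
#'   the complement (default 2).
#' @return a `binary_mask`.
#' @export
background_from_objects <- function(masks, erode_voxels = 2L) {
  stopifnot(length(masks) >= 1L)
  arrs <- lapply(masks, as_mask_array)
  d <- dim(arrs[[1]])
  fg <- Reduce(`|`, arrs)
  bg <- !fg
  for (i in seq_len(erode_voxels))
    bg <- array(cpp_erode6(bg, d), dim = d)
  binary_mask(bg, provenance = list(erode_voxels = erode_voxels))
}

#' Per-cell expression in arbitrary units (AU)
#'
#' The noise floor and its standard deviation are measured over the
#' background region; mask voxels whose intensity rises more than two
#' standard deviations above the floor are averaged, and the mean is normalized by
#' the maximum bit-depth intensity, giving AU in `[0, 1]`. When no voxel
#' clears the gate the result is 0 with `n_voxels_included = 0`.
#'
#' @param marker a `channel_stack` of the expression channel.
#' @param mask 3D cell mask (`binary_mask` or logical array), non-empty.
#' @param background background region, disjoint from `mask`, non-empty.
#' @param snr_sd gate in background standard deviations above the noise
#'   floor (default 2).
#' @param aggregate `"mean"` (default), `"median"` or `"sum"` of included
#'   intensities before normalization.
#' @return list of class `expression_result` with `au`,
#'   `n_voxels_included`, `noise_floor`, `noise_sd`.
#' @export
quantify_au <- function(marker, mask, background, snr_sd = 2,
                        aggregate = c("mean", "median", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(marker, "channel_stack"))
  m <- as_mask_array(mask)
  b <- as_mask_array(background)
  if (!identical(dim(m), dim(marker$voxels)) ||
      !identical(dim(b), dim(marker$voxels)))
    stop("mask/background shape must match the marker stack")
  if (!any(m)) stop("empty cell mask")
  if (!any(b)) stop("empty background region")
  if (any(m & b)) stop("mask and background must be disjoint")
  vals_bg <- marker$voxels[b]
  noise_floor <- mean(vals_bg)
  noise_sd <- sd(vals_bg)
  if (is.na(noise_sd)) noise_sd <- 0
  vals <- marker$voxels[m]
  included <- vals > noise_floor + snr_sd * noise_sd
  n_inc <- sum(included)
  maxI <- 2^marker$bit_depth - 1
  au <- if (n_inc == 0L) 0 else {
    agg <- switch(aggregate,
                  mean = mean(vals[included]),
                  median = median(vals[included]),
                  sum = sum(vals[included]))
    agg / maxI
  }
  structure(list(au = au, n_voxels_included = n_inc,
                 noise_floor = noise_floor, noise_sd = noise_sd),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression> %.4f AU over %d voxels (noise floor %.1f +/- %.1f)\n",
              x$au, x$n_voxels_included, x$noise_floor, x$noise_sd))
  invisible(x)
}
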