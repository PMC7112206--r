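#' Specification of a synthetic confocal scene
#'
#' Describes a multi-channel 3D scene of spherical cells (a nucleus sphere
#' inside a soma sphere) with known live/dead and marker-positivity labels,
#' rendered with a Gaussian point-spread function, signal-dependent and
#' additive noise, and the bidirectional scan-line mismatch artifact of
#' resonant confocal scanning. Defaults mirror a live-imaging acquisition at
#' 1.24 um isotropic voxel pitch, scaled down so suites run in seconds.
#'
#' @param shape_voxels integer length-3 `(nz, ny, nx)`.
#' @param voxel_size_um numeric length-3 voxel pitch in um `(z, y, x)`.
#' @param bit_depth 8, 12 or 16.
#' @param n_cells number of cells to place (>= 0).
#' @param fraction_dead fraction of cells rendered dead, in `[0, 1]`.
#' @param fraction_marker_positive fraction of *live* cells rendered
#'   marker-positive, in `[0, 1]`.
#' @param nucleus_radius_um length-2 range of nucleus radii (um).
#' @param soma_radius_um length-2 range of soma radii (um).
#' @param min_center_spacing_um minimum distance between cell centers (um).
#' @param psf_sigma_um Gaussian PSF sigma per axis `(z, y, x)` in um; 0
#'   disables blurring.
#' @param background_level background offset as a fraction of the dynamic
#'   range, in `[0, 1)`.
#' @param shot_noise_scale variance of the signal-dependent noise per digital
#'   number of signal (Gaussian approximation to shot noise); 0 disables.
#' @param read_noise_sd standard deviation of additive Gaussian read noise in
#'   digital numbers; 0 disables.
#' @param mismatch_shift_px integer x-shift applied to odd y scan lines.
#' @param marker_intensity_range length-2 range of true marker mean
#'   intensities for positive cells, as fractions of the dynamic range.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape_voxels = c(60L, 192L, 192L),
                       voxel_size_um = c(1.24, 1.24, 1.24),
                       bit_depth = 12L,
                       n_cells = 25L,
                       fraction_dead = 0.1,
                       fraction_marker_positive = 0.3,
                       nucleus_radius_um = c(3, 4.5),
                       soma_radius_um = c(5, 7),
                       min_center_spacing_um = 20,
                       psf_sigma_um = c(1.0, 0.5, 0.5),
                       background_level = 0.02,
                       shot_noise_scale = 1,
                       read_noise_sd = 15,
                       mismatch_shift_px = 1L,
                       marker_intensity_range = c(0.5, 0.85),
                       rng_seed = 1L) {
  if (mismatch_shift_px != round(mismatch_shift_px))
    stop("mismatch_shift_px must be an integer")
  spec <- list(shape_voxels = as.integer(shape_voxels),
               voxel_size_um = as.numeric(voxel_size_um),
               bit_depth = as.integer(bit_depth),
               n_cells = as.integer(n_cells),
               fraction_dead = fraction_dead,
               fraction_marker_positive = fraction_marker_positive,
               nucleus_radius_um = as.numeric(nucleus_radius_um),
               soma_radius_um = as.numeric(soma_radius_um),
               min_center_spacing_um = min_center_spacing_um,
               psf_sigma_um = as.numeric(psf_sigma_um),
               background_level = background_level,
               shot_noise_scale = shot_noise_scale,
               read_noise_sd = read_noise_sd,
               mismatch_shift_px = as.integer(mismatch_shift_px),
               marker_intensity_range = as.numeric(marker_intensity_range),
               rng_seed = as.integer(rng_seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (length(shape_voxels) != 3L || any(shape_voxels < 1L))
      stop("shape_voxels must be 3 positive integers; zero-volume shape")
    if (any(voxel_size_um <= 0)) stop("voxel_size_um must be positive")
    if (!bit_depth %in% c(8L, 12L, 16L)) stop("bit_depth must be 8, 12 or 16")
    if (n_cells < 0L) stop("n_cells must be >= 0")
    if (fraction_dead < 0 || fraction_dead > 1)
      stop("fraction_dead must be in [0, 1]")
    if (fraction_marker_positive < 0 || fraction_marker_positive > 1)
      stop("fraction_marker_positive must be in [0, 1]")
    if (any(nucleus_radius_um <= 0) || any(soma_radius_um <= 0))
      stop("radii must be strictly positive")
    if (nucleus_radius_um[1] > nucleus_radius_um[2] ||
        soma_radius_um[1] > soma_radius_um[2])
      stop("radius ranges must be (min, max)")
    if (nucleus_radius_um[1] > soma_radius_um[2])
      stop("nucleus radius must not exceed soma radius")
    if (min_center_spacing_um <= 0) stop("min_center_spacing_um must be > 0")
    if (any(psf_sigma_um < 0)) stop("psf_sigma_um must be >= 0")
    if (background_level < 0 || background_level >= 1)
      stop("background_level must be in [0, 1)")
    if (shot_noise_scale < 0 || read_noise_sd < 0)
      stop("noise parameters must be >= 0")
    if (mismatch_shift_px != round(mismatch_shift_px))
      stop("mismatch_shift_px must be an integer")
  })
  invisible(spec)
}

# Deterministic RNG scope: run expr under the given seed, restoring the
# caller's RNG state afterwards.
with_scene_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Rejection-sample n cell centers (um coordinates) with a minimum pairwise
# spacing, keeping each center at least `margin_um` from every face so that
# somata render fully inside the volume.
place_centers <- function(extent_um, n, min_spacing_um, margin_um,
                          max_attempts = 10000L * max(n, 1L)) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  lo <- rep(margin_um, 3)
  hi <- extent_um - margin_um
  if (any(hi <= lo))
    stop("volume too small for the requested soma radius margin")
  centers <- matrix(NA_real_, nrow = n, ncol = 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("scene too crowded: could not place ", n, " cells at ",
           min_spacing_um, " um spacing")
    cand <- lo + runif(3) * (hi - lo)
    ok <- TRUE
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2 +
            (centers[seq_len(placed), 3] - cand[3])^2
      ok <- all(d2 >= min_spacing_um^2)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  centers
}

# Linear indices (1-based, dims nz,ny,nx) of the voxels inside a sphere with
# center in um and radius in um; anisotropic voxels handled per axis.
sphere_indices <- function(d, center_um, radius_um, voxel_size_um) {
  cv <- center_um / voxel_size_um + 0.5  # continuous 1-based voxel coords
  rv <- radius_um / voxel_size_um
  idx <- lapply(1:3, function(k) {
    lo <- max(1L, floor(cv[k] - rv[k]))
    hi <- min(d[k], ceiling(cv[k] + rv[k]))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(idx) == 0L)) return(integer(0))
  dz2 <- ((idx[[1]] - cv[1]) * voxel_size_um[1])^2
  dy2 <- ((idx[[2]] - cv[2]) * voxel_size_um[2])^2
  dx2 <- ((idx[[3]] - cv[3]) * voxel_size_um[3])^2
  inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= radius_um^2
  w <- which(inside)
  if (length(w) == 0L) return(integer(0))
  sub <- arrayInd(w, dim(inside))
  idx[[1]][sub[, 1]] +
    (d[1]) * (idx[[2]][sub[, 2]] - 1L) +
    (d[1] * d[2]) * (idx[[3]][sub[, 3]] - 1L)
}

gaussian_blur_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  x <- as.numeric(arr)
  for (axis in 0:2) {
    s <- sigma_vox[axis + 1]
    if (s > 0) {
      r <- max(1L, ceiling(3 * s))
      k <- dnorm(seq(-r, r), sd = s)
      k <- k / sum(k)
      x <- cpp_conv_axis(x, d, k, axis)
    }
  }
  array(x, dim = d)
}

#' Apply the bidirectional scan-line mismatch artifact
#'
#' Translates every odd-indexed y scan line (0-based row parity, i.e. the
#' second, fourth, ... rows) by `shift_px` voxels along x, emulating the
#' line-to-line offset of bidirectional resonant scanning. Vacated pixels are
#' filled with `fill`.
#'
#' @param stack a `channel_stack` or 3D numeric array.
#' @param shift_px integer shift; `|shift_px|` must be smaller than the
#'   x-dimension.
#' @param fill value for vacated pixels (the channel's background level).
#' @return object of the same type as `stack`.
#' @export
apply_bidirectional_mismatch <- function(stack, shift_px, fill = 0) {
  a <- as_stack_array(stack)
  out <- shift_odd_lines(a, shift_px, fill)
  if (inherits(stack, "channel_stack")) {
    stack$voxels <- out
    stack
  } else out
}

shift_odd_lines <- function(a, shift_px, fill) {
  if (shift_px != round(shift_px))
    stop("shift_px must be an integer (subpixel mismatch not supported)")
  shift_px <- as.integer(shift_px)
  d <- dim(a)
  if (abs(shift_px) >= d[3]) stop("|shift_px| must be < x-dimension")
  if (shift_px == 0L) return(a)
  odd <- seq(2L, d[2], by = 2L)  # 0-based odd rows
  if (length(odd) == 0L) return(a)
  nx <- d[3]
  shifted <- array(fill, dim = c(d[1], length(odd), nx))
  if (shift_px > 0L) {
    shifted[, , (shift_px + 1L):nx] <- a[, odd, 1L:(nx - shift_px)]
  } else {
    s <- -shift_px
    shifted[, , 1L:(nx - s)] <- a[, odd, (s + 1L):nx]
  }
  a[, odd, ] <- shifted
  a
}

#' Generate a synthetic multi-channel confocal scene with ground truth
#'
#' Renders five co-registered channels: `nuclei` (all nuclei), `live` (somata
#' of live cells), `dead` (nuclei of dead cells), `marker` (somata of
#' marker-positive live cells at each cell's true mean intensity) and
#' `brightfield` (all somata darker than a mid-grey background). Each
#' fluorescence channel is blurred with the Gaussian PSF, offset by the
#' background level, corrupted with signal-dependent plus additive Gaussian
#' noise, clipped to the bit depth and finally distorted with the
#' bidirectional scan-line mismatch. Marker positivity is defined only among
#' live cells, so `is_marker_positive` is always `FALSE` for dead cells.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `stacks` (named list of `channel_stack`),
#'   `truth` (ground-truth `data.frame`, one row per cell) and `spec`.
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  d <- spec$shape_voxels
  maxI <- 2^spec$bit_depth - 1
  extent_um <- d * spec$voxel_size_um
  with_scene_rng(spec$rng_seed, {
    n <- spec$n_cells
    margin <- spec$soma_radius_um[2]
    centers <- place_centers(extent_um, n, spec$min_center_spacing_um, margin)
    r_nuc <- if (n) runif(n, spec$nucleus_radius_um[1], spec$nucleus_radius_um[2]) else numeric(0)
    r_soma <- if (n) pmax(runif(n, spec$soma_radius_um[1], spec$soma_radius_um[2]), r_nuc) else numeric(0)
    n_dead <- round(spec$fraction_dead * n)
    is_dead <- rep(FALSE, n)
    if (n_dead > 0) is_dead[sample.int(n, n_dead)] <- TRUE
    live_idx <- which(!is_dead)
    n_pos <- round(spec$fraction_marker_positive * length(live_idx))
    is_pos <- rep(FALSE, n)
    if (n_pos > 0) is_pos[sample(live_idx, n_pos)] <- TRUE
    marker_mean <- rep(0, n)
    if (n_pos > 0)
      marker_mean[is_pos] <- runif(n_pos, spec$marker_intensity_range[1],
                                   spec$marker_intensity_range[2]) * maxI

    amp <- 0.6 * maxI
    render <- function(which_cells, radii, amplitudes, base = 0) {
      a <- array(base, dim = d)
      for (i in which_cells) {
        ii <- sphere_indices(d, centers[i, ], radii[i], spec$voxel_size_um)
        if (length(ii)) a[ii] <- pmax(a[ii], amplitudes[i])
      }
      a
    }
    raw <- list(
      nuclei = render(seq_len(n), r_nuc, rep(amp, n)),
      live = render(which(!is_dead), r_soma, rep(amp, n)),
      dead = render(which(is_dead), r_nuc, rep(amp, n)),
      marker = render(which(is_pos), r_soma, marker_mean)
    )
    bg_dn <- spec$background_level * maxI
    sigma_vox <- spec$psf_sigma_um / spec$voxel_size_um

    finalize <- function(a, background_dn, fill = round(background_dn)) {
      if (any(sigma_vox > 0)) a <- gaussian_blur_3d(a, sigma_vox)
      a <- a + background_dn
      if (spec$shot_noise_scale > 0)
        a <- a + rnorm(length(a)) * sqrt(spec$shot_noise_scale * pmax(a, 0))
      if (spec$read_noise_sd > 0)
        a <- a + rnorm(length(a), sd = spec$read_noise_sd)
      a <- round(pmin(pmax(a, 0), maxI))
      shift_odd_lines(a, spec$mismatch_shift_px, fill)
    }

    stacks <- list()
    for (role in c("nuclei", "live", "dead", "marker")) {
      stacks[[role]] <- channel_stack(finalize(raw[[role]], bg_dn),
                                      spec$voxel_size_um, spec$bit_depth, role)
      raw[[role]] <- NULL
    }
    # brightfield: somata absorb against a mid-grey transmitted background
    bf <- array(0.5 * maxI, dim = d)
    for (i in seq_len(n)) {
      ii <- sphere_indices(d, centers[i, ], r_soma[i], spec$voxel_size_um)
      if (length(ii)) bf[ii] <- 0.35 * maxI
    }
    stacks$brightfield <- channel_stack(
      finalize(bf, 0, fill = round(0.5 * maxI)),
      spec$voxel_size_um, spec$bit_depth, "brightfield")

    centers_vox <- sweep(centers, 2, spec$voxel_size_um, "/") + 0.5
    truth <- data.frame(
      cell_id = seq_len(n),
      centroid_z = centers_vox[, 1],
      centroid_y = centers_vox[, 2],
      centroid_x = centers_vox[, 3],
      nucleus_radius_um = r_nuc,
      soma_radius_um = r_soma,
      is_dead = is_dead,
      is_marker_positive = is_pos,
      true_marker_mean_intensity = marker_mean
    )
    list(stacks = stacks, truth = truth, spec = spec)
  })
}

#' Write a scene (channels, ground truth, spec) to a directory
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (role in names(scene$stacks))
    write_stack_tiff(scene$stacks[[role]], file.path(dir, paste0(role, ".tif")))
  write.csv(scene$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  write_scene_spec(scene$spec, file.path(dir, "scene_spec.yaml"))
  invisible(dir)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scene_spec, vals)
}

#' Round-trip a scene spec through YAML
#'
#' @param spec a [scene_spec()].
#' @param path YAML file path.
#' @return `path` (write) or a `scene_spec` (read), invisibly for write.
#' @export
write_scene_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}
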