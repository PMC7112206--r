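#' @useDynLib viacool, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov cov dnorm median pnorm rnorm runif sd setNames
#'   shapiro.test kruskal.test TukeyHSD uniroot var
#' @importFrom utils read.csv write.csv modifyList
NULL

CHANNEL_ROLES <- c("nuclei", "live", "dead", "marker", "brightfield")

#' Multi-channel 3D intensity stack container
#'
#' A `channel_stack` holds one channel of a confocal volume as a 3D numeric
#' array in `(z, y, x)` order together with its acquisition metadata. All
#' intensities must lie in `[0, 2^bit_depth - 1]`.
#'
#' @param voxels 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param voxel_size_um numeric length-3, voxel pitch in micrometres for
#'   `(z, y, x)`; all components strictly positive.
#' @param bit_depth integer, one of 8, 12 or 16.
#' @param channel_role one of `"nuclei"`, `"live"`, `"dead"`, `"marker"`,
#'   `"brightfield"`.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(voxels, voxel_size_um, bit_depth, channel_role) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array in (z, y, x) order")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 3L ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be 3 strictly positive values (z, y, x)")
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("bit_depth must be 8, 12 or 16")
  channel_role <- match.arg(channel_role, CHANNEL_ROLES)
  maxI <- 2^bit_depth - 1
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > maxI)
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  structure(
    list(voxels = voxels,
         voxel_size_um = as.numeric(voxel_size_um),
         bit_depth = as.integer(bit_depth),
         channel_role = channel_role),
    class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<channel_stack> role=%s  %d x %d x %d voxels (z,y,x)  %d-bit\n",
              x$channel_role, d[1], d[2], d[3], x$bit_depth))
  cat(sprintf("  voxel size (um): %.3g x %.3g x %.3g   intensity range [%g, %g]\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask over a stack
#'
#' @param voxels 3D logical array in `(z, y, x)` order.
#' @param provenance list recording how the mask was made (e.g. threshold
#'   value, source channel role, degenerate flag).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, provenance = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("voxels must be a 3D logical array")
  structure(list(voxels = voxels, provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, format, ""),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$voxels
  else if (is.array(mask) && is.logical(mask)) mask
  else stop("expected a binary_mask or logical array")
}

as_stack_array <- function(stack) {
  if (inherits(stack, "channel_stack")) stack$voxels
  else if (is.array(stack) && is.numeric(stack)) stack
  else stop("expected a channel_stack or numeric array")
}

#' Maximum-intensity projection of a stack
#'
#' Collapses the z-axis by the per-pixel maximum, the standard rendering of
#' through-thickness confocal volumes.
#'
#' @param stack a `channel_stack` (or 3D numeric array).
#' @return a `(ny, nx)` numeric matrix.
#' @export
project_max <- function(stack) {
  a <- as_stack_array(stack)
  apply(a, c(2, 3), max)
}

#' Write a stack to a multi-page TIFF file
#'
#' One page per z-slice; intensities are stored at the stack's bit depth
#' (12-bit data is written in 16-bit containers, as confocal software does).
#'
#' @param stack a `channel_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  maxI <- 2^stack$bit_depth - 1
  bps <- if (stack$bit_depth == 8L) 8L else 16L
  store_max <- 2^bps - 1
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- stack$voxels[z, , , drop = TRUE]
    dim(m) <- d[2:3]
    # writeTIFF expects [0,1]; preserve raw counts across the container depth
    round(m) / store_max
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF file as a channel stack
#'
#' @param path TIFF file path.
#' @param voxel_size_um voxel pitch `(z, y, x)` in micrometres.
#' @param bit_depth bit depth of the data (8, 12 or 16).
#' @param channel_role channel role of the data.
#' @return a `channel_stack`.
#' @export
read_stack_tiff <- function(path, voxel_size_um, bit_depth, channel_role) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- if (bit_depth == 8L) 8L else 16L
  store_max <- 2^bps - 1
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(length(pages), ny, nx))
  for (z in seq_along(pages)) vox[z, , ] <- round(pages[[z]] * store_max)
  channel_stack(vox, voxel_size_um, bit_depth, channel_role)
}
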