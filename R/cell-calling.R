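#' Detect blob-like 3D objects in a binary mask
#'
#' Labels connected components and keeps those passing the blob screens used
#' for nuclei and somata: a minimum voxel count, a minimum extent ratio
#' (voxel count divided by bounding-box volume; a digitized sphere has extent
#' about pi/6 = 0.52, so the default 0.3 admits blob-like objects while
#' rejecting sparse or branched ones), and optionally a principal-axis
#' elongation cap that removes filamentous objects (extent alone passes an
#' axis-aligned filament, whose extent is 1).
#'
#' Bounding boxes are half-open along each axis: `z0` is the first voxel
#' (1-based) and `z1` is one past the last, so boxes sharing only a face do
#' not overlap.
#'
#' @param mask a `binary_mask` or logical array.
#' @param min_extent_ratio minimum extent ratio in `(0, 1]`.
#' @param min_voxels minimum component size in voxels.
#' @param connectivity 6, 18 or 26.
#' @param max_elongation optional cap on the ratio of largest to smallest
#'   principal-axis spread (e.g. 3); `NULL` disables the screen.
#' @return A `data.frame` (class `detected_objects`), one row per object,
#'   sorted by `(z0, y0, x0)`, with columns `object_id`, `z0,z1,y0,y1,x0,x1`,
#'   `centroid_z/y/x`, `voxel_count`, `extent_ratio`. The stack dimensions
#'   and source channel role are carried as attributes.
#' @export
detect_objects <- function(mask, min_extent_ratio = 0.3, min_voxels = 30L,
                           connectivity = 26L, max_elongation = NULL) {
  a <- as_mask_array(mask)
  d <- dim(a)
  role <- if (inherits(mask, "binary_mask"))
    mask$provenance$channel_role else NA_character_
  empty <- data.frame(object_id = integer(0),
                      z0 = integer(0), z1 = integer(0),
                      y0 = integer(0), y1 = integer(0),
                      x0 = integer(0), x1 = integer(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0),
                      voxel_count = integer(0), extent_ratio = numeric(0))
  finish <- function(df) {
    df <- df[order(df$z0, df$y0, df$x0), , drop = FALSE]
    df$object_id <- seq_len(nrow(df))
    rownames(df) <- NULL
    structure(df, stack_dim = d, channel_role = role,
              class = c("detected_objects", "data.frame"))
  }
  if (!any(a)) return(finish(empty))

  labels <- cpp_label3d(a, d, as.integer(connectivity))
  fg <- which(labels > 0L)
  lab <- labels[fg]
  co <- arrayInd(fg, d)
  zs <- co[, 1]; ys <- co[, 2]; xs <- co[, 3]
  f <- factor(lab)
  agg <- data.frame(
    z0 = tapply(zs, f, min), z1 = tapply(zs, f, max) + 1L,
    y0 = tapply(ys, f, min), y1 = tapply(ys, f, max) + 1L,
    x0 = tapply(xs, f, min), x1 = tapply(xs, f, max) + 1L,
    centroid_z = tapply(zs, f, mean),
    centroid_y = tapply(ys, f, mean),
    centroid_x = tapply(xs, f, mean),
    voxel_count = as.integer(table(f)))
  agg$extent_ratio <- agg$voxel_count /
    ((agg$z1 - agg$z0) * (agg$y1 - agg$y0) * (agg$x1 - agg$x0))
  keep <- agg$voxel_count >= min_voxels & agg$extent_ratio >= min_extent_ratio
  if (!is.null(max_elongation)) {
    elong <- vapply(levels(f), function(l) {
      sel <- lab == as.integer(l)
      if (sum(sel) < 2L) return(1)
      ev <- eigen(cov(cbind(zs[sel], ys[sel], xs[sel])),
                  symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 1 / 12)  # single-voxel variance floor
      sqrt(max(ev) / min(ev))
    }, numeric(1))
    keep <- keep & elong <= max_elongation
  }
  agg <- agg[keep, , drop = FALSE]
  if (nrow(agg) == 0L) return(finish(empty))
  agg$object_id <- NA_integer_
  finish(agg)
}

bbox_cols <- c("z0", "z1", "y0", "y1", "x0", "x1")

#' Do two detected objects' bounding boxes overlap?
#'
#' Half-open interval intersection on all three axes; boxes that share only
#' a face or an edge do not overlap.
#'
#' @param a,b single rows of [detect_objects()] output (or any list with
#'   `z0,z1,y0,y1,x0,x1`).
#' @param check_shape when both carry a `stack_dim` attribute, require the
#'   source stacks to have identical shape.
#' @return logical scalar.
#' @export
bboxes_overlap <- function(a, b, check_shape = TRUE) {
  if (check_shape) {
    da <- attr(a, "stack_dim"); db <- attr(b, "stack_dim")
    if (!is.null(da) && !is.null(db) && !identical(da, db))
      stop("objects come from stacks of different shape")
  }
  a$z0 < b$z1 && b$z0 < a$z1 &&
    a$y0 < b$y1 && b$y0 < a$y1 &&
    a$x0 < b$x1 && b$x0 < a$x1
}

# Overlap matrix between two object tables: rows of A x rows of B.
bbox_overlap_matrix <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(matrix(FALSE, nrow(A), nrow(B)))
  da <- attr(A, "stack_dim"); db <- attr(B, "stack_dim")
  if (!is.null(da) && !is.null(db) && !identical(da, db))
    stop("objects come from stacks of different shape")
  ov <- function(lo_a, hi_a, lo_b, hi_b)
    outer(lo_a, hi_b, "<") & t(outer(lo_b, hi_a, "<"))
  ov(A$z0, A$z1, B$z0, B$z1) &
    ov(A$y0, A$y1, B$y0, B$y1) &
    ov(A$x0, A$x1, B$x0, B$x1)
}

#' Call live/dead status and marker positivity per nucleus
#'
#' Implements the bounding-box colocalization rule: a nucleus is dead when
#' its box overlaps at least one dead-channel object, and marker-positive
#' when it is not dead and its box overlaps at least one marker-channel
#' object (positivity is defined only among live cells, so a nucleus
#' colocalizing with both the marker and the dead stain is called dead, not
#' positive). Overlap with several marker objects still counts once.
#'
#' @param nuclei,dead,markers [detect_objects()] tables from co-registered
#'   stacks (the dead and marker tables may be empty).
#' @return A `data.frame` (class `cell_call_table`) with one row per
#'   nucleus: `nucleus_id`, `is_dead`, `is_marker_positive`, and the
#'   supporting `dead_object_ids` / `marker_object_ids` as comma-separated
#'   strings.
#' @export
call_cells <- function(nuclei, dead, markers) {
  n <- nrow(nuclei)
  ov_dead <- bbox_overlap_matrix(nuclei, dead)
  ov_mark <- bbox_overlap_matrix(nuclei, markers)
  is_dead <- if (ncol(ov_dead)) apply(ov_dead, 1, any) else rep(FALSE, n)
  has_marker <- if (ncol(ov_mark)) apply(ov_mark, 1, any) else rep(FALSE, n)
  ids <- function(ovrow, tab)
    paste(tab$object_id[ovrow], collapse = ",")
  out <- data.frame(
    nucleus_id = nuclei$object_id,
    is_dead = is_dead,
    is_marker_positive = !is_dead & has_marker,
    dead_object_ids = vapply(seq_len(n), function(i)
      ids(ov_dead[i, ], dead), character(1)),
    marker_object_ids = vapply(seq_len(n), function(i)
      ids(ov_mark[i, ], markers), character(1)))
  structure(out, class = c("cell_call_table", "data.frame"))
}

#' Percentage of marker-positive cells
#'
#' @param table a [call_cells()] table.
#' @param denominator `"live"` (default; the call rule defines positivity
#'   only among live nuclei) or `"all"` nuclei.
#' @return percentage in `[0, 100]`.
#' @export
percent_positive <- function(table, denominator = c("live", "all")) {
  denominator <- match.arg(denominator)
  if (nrow(table) == 0L) stop("empty call table")
  denom <- if (denominator == "live") sum(!table$is_dead) else nrow(table)
  if (denom == 0L) stop("no live nuclei: percent positive undefined")
  100 * sum(table$is_marker_positive) / denom
}

#' Live/dead viability from detected objects
#'
#' Automates the live/dead count of a calcein AM / ethidium homodimer-1
#' assay: live cells are live-channel objects whose boxes overlap no
#' dead-channel object (a calcein-positive cell that also shows a dead
#' nucleus is counted dead), and dead cells are the dead-channel objects.
#'
#' @param live_objects,dead_objects [detect_objects()] tables.
#' @return list of class `viability_result` with `n_live`, `n_dead`,
#'   `viability_pct`.
#' @export
viability <- function(live_objects, dead_objects) {
  n_dead <- nrow(dead_objects)
  ov <- bbox_overlap_matrix(live_objects, dead_objects)
  n_live <- if (ncol(ov)) sum(!apply(ov, 1, any)) else nrow(live_objects)
  if (n_live + n_dead == 0L)
    stop("no objects: viability undefined")
  structure(list(n_live = n_live, n_dead = n_dead,
                 viability_pct = 100 * n_live / (n_live + n_dead)),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability> %d live / %d dead  ->  %.1f%% viable\n",
              x$n_live, x$n_dead, x$viability_pct))
  invisible(x)
}
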