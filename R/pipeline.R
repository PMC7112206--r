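#' Experiment configuration
#'
#' Describes a multi-group experiment over synthetic scenes (or scene
#' directories previously written with [write_scene()]): per-group scene
#' parameters, the analysis mode, preprocessing and calling parameters, and
#' a single top-level seed from which every per-sample seed is derived
#' deterministically.
#'
#' @param groups named list; each element a list with either
#'   `n_samples` (integer) plus optional `scene` (list of [scene_spec()]
#'   overrides) for synthetic groups, or `paths` (character vector of scene
#'   directories); optional `metadata` (e.g. `temperature_C`, `delay_h`,
#'   `duration_h`, `injured`).
#' @param mode `"viability"`, `"caspase"`, `"ros"` or `"calpastatin"`.
#' @param alpha significance level for the group comparison.
#' @param seed top-level integer seed.
#' @param scene_defaults [scene_spec()] overrides shared by all groups.
#' @param preprocess list: `median_radius_px`, `min_voxels` (de-speckle),
#'   `connectivity`.
#' @param calling list: `min_extent_ratio`, `min_voxels`, `connectivity`,
#'   `max_elongation`.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(groups,
                              mode = c("viability", "caspase", "ros",
                                       "calpastatin"),
                              alpha = 0.05, seed = 1L,
                              scene_defaults = list(),
                              preprocess = list(), calling = list()) {
  mode <- match.arg(mode)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$paths) && is.null(gr$n_samples))
      stop("group '", g, "' needs n_samples (synthetic) or paths")
  }
  pp <- modifyList(list(median_radius_px = 1L, min_voxels = 27L,
                        connectivity = 26L), preprocess)
  cl <- modifyList(list(min_extent_ratio = 0.3, min_voxels = 30L,
                        connectivity = 26L, max_elongation = NULL),
                   calling)
  structure(list(groups = groups, mode = mode, alpha = alpha,
                 seed = as.integer(seed), scene_defaults = scene_defaults,
                 preprocess = pp, calling = cl),
            class = "experiment_config")
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir directory containing `scene_spec.yaml`, per-channel TIFFs and
#'   optionally `ground_truth.csv`.
#' @return a scene list (`stacks`, `truth` or `NULL`, `spec`).
#' @export
read_scene <- function(dir) {
  spec <- read_scene_spec(file.path(dir, "scene_spec.yaml"))
  stacks <- list()
  for (role in CHANNEL_ROLES) {
    f <- file.path(dir, paste0(role, ".tif"))
    if (file.exists(f))
      stacks[[role]] <- read_stack_tiff(f, spec$voxel_size_um,
                                        spec$bit_depth, role)
  }
  truth_file <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_file)) read.csv(truth_file) else NULL
  list(stacks = stacks, truth = truth, spec = spec)
}

scene_mask <- function(scene, role, pp) {
  if (is.null(scene$stacks[[role]]))
    stop("required channel '", role, "' missing from scene")
  preprocess_channel(scene$stacks[[role]],
                     shift_px = scene$spec$mismatch_shift_px,
                     median_radius_px = pp$median_radius_px,
                     min_voxels = pp$min_voxels,
                     connectivity = pp$connectivity)
}

scene_objects <- function(mask, cl) {
  detect_objects(mask, min_extent_ratio = cl$min_extent_ratio,
                 min_voxels = cl$min_voxels,
                 connectivity = cl$connectivity,
                 max_elongation = cl$max_elongation)
}

#' Analyse one scene under a given mode
#'
#' Runs the conditioning chain (mismatch correction, median filter,
#' histogram binarization, de-speckling), detects objects and computes the
#' mode's per-sample outcome: viability % (`viability`), percent
#' marker-positive (`caspase`/`ros`), or mean per-cell AU (`calpastatin`).
#'
#' @param scene a scene from [generate_scene()] or [read_scene()].
#' @param mode analysis mode.
#' @param preprocess,calling parameter lists as in [experiment_config()].
#' @return list with `value` plus mode-specific detail tables.
#' @export
analyze_scene <- function(scene, mode = c("viability", "caspase", "ros",
                                          "calpastatin"),
                          preprocess = list(), calling = list()) {
  mode <- match.arg(mode)
  pp <- modifyList(list(median_radius_px = 1L, min_voxels = 27L,
                        connectivity = 26L), preprocess)
  cl <- modifyList(list(min_extent_ratio = 0.3, min_voxels = 30L,
                        connectivity = 26L, max_elongation = NULL), calling)
  if (mode == "viability") {
    live <- scene_objects(scene_mask(scene, "live", pp), cl)
    dead <- scene_objects(scene_mask(scene, "dead", pp), cl)
    v <- viability(live, dead)
    list(value = v$viability_pct, viability = v,
         objects = list(live = live, dead = dead))
  } else if (mode %in% c("caspase", "ros")) {
    nuclei <- scene_objects(scene_mask(scene, "nuclei", pp), cl)
    dead <- scene_objects(scene_mask(scene, "dead", pp), cl)
    markers <- scene_objects(scene_mask(scene, "marker", pp), cl)
    calls <- call_cells(nuclei, dead, markers)
    list(value = percent_positive(calls), calls = calls,
         objects = list(nuclei = nuclei, dead = dead, marker = markers))
  } else {
    analyze_expression(scene, pp, cl)
  }
}

# Calpastatin-type expression analysis: per detected nucleus, outline the
# cell on the brightfield slice at the nucleus centroid, extrude over the
# DAPI z-extent, and quantify the marker channel against a global noise
# floor. The per-sample value is the mean AU over quantified cells.
analyze_expression <- function(scene, pp, cl) {
  nuc_mask <- scene_mask(scene, "nuclei", pp)
  marker_mask <- scene_mask(scene, "marker", pp)
  nuclei <- scene_objects(nuc_mask, cl)
  if (nrow(nuclei) == 0L) stop("no nuclei detected for expression analysis")
  bf <- correct_bidirectional_mismatch(scene$stacks$brightfield,
                                       scene$spec$mismatch_shift_px,
                                       fill = 2^scene$spec$bit_depth / 2)
  bf <- denoise_median(bf, pp$median_radius_px)
  marker <- correct_bidirectional_mismatch(scene$stacks$marker,
                                           scene$spec$mismatch_shift_px)
  marker <- denoise_median(marker, pp$median_radius_px)
  bg <- background_from_objects(list(nuc_mask, marker_mask))
  d <- dim(nuc_mask$voxels)
  half_w <- ceiling(1.5 * max(scene$spec$soma_radius_um) /
                      min(scene$spec$voxel_size_um[2:3]))
  results <- vector("list", nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    zc <- max(1L, min(d[1], round(nuclei$centroid_z[i])))
    yc <- round(nuclei$centroid_y[i]); xc <- round(nuclei$centroid_x[i])
    ys <- max(1L, yc - half_w):min(d[2], yc + half_w)
    xs <- max(1L, xc - half_w):min(d[3], xc + half_w)
    plane <- bf$voxels[zc, ys, xs]
    dim(plane) <- c(length(ys), length(xs))
    init <- nuc_mask$voxels[zc, ys, xs]
    dim(init) <- dim(plane)
    if (!any(init)) next
    outline_w <- segment_cell_levelset(plane, init)
    outline <- matrix(FALSE, d[2], d[3])
    outline[ys, xs] <- outline_w
    cell3d <- build_cell_mask_3d(outline, nuc_mask)
    if (isTRUE(cell3d$provenance$empty)) next
    bg_use <- binary_mask(bg$voxels & !cell3d$voxels)
    if (!any(bg_use$voxels)) next
    er <- quantify_au(marker, cell3d, bg_use)
    results[[i]] <- data.frame(nucleus_id = nuclei$object_id[i],
                               au = er$au,
                               n_voxels_included = er$n_voxels_included,
                               noise_floor = er$noise_floor,
                               noise_sd = er$noise_sd)
  }
  per_cell <- do.call(rbind, results[!vapply(results, is.null, logical(1))])
  if (is.null(per_cell) || nrow(per_cell) == 0L)
    stop("no cell could be quantified")
  list(value = mean(per_cell$au), per_cell = per_cell,
       objects = list(nuclei = nuclei))
}

derive_seed <- function(seed, group_idx, sample_idx) {
  as.integer((as.numeric(seed) * 10007 + group_idx * 131 + sample_idx * 7)
             %% 2147483647)
}

#' Run a configured multi-group experiment end to end
#'
#' Simulate (or load) every sample, analyse each scene under the configured
#' mode, compare groups, and optionally write per-sample and group-level
#' CSVs, a JSON report and a parameter log. Reruns with an identical config
#' produce identical outputs for synthetic inputs.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory; when given, writes
#'   `samples.csv`, `groups.csv`, `report.json` and `run_log.txt`.
#' @return list of class `experiment_result`: `samples` (per-sample
#'   data.frame), `report` (a `comparison_report`), `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  log_lines <- c(sprintf("viacool run: mode=%s alpha=%g seed=%d",
                         config$mode, config$alpha, config$seed))
  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    gr <- config$groups[[gi]]
    if (!is.null(gr$paths)) {
      scenes <- lapply(gr$paths, read_scene)
      seeds <- rep(NA_integer_, length(scenes))
    } else {
      seeds <- vapply(seq_len(gr$n_samples), function(si)
        derive_seed(config$seed, gi, si), integer(1))
      scenes <- lapply(seeds, function(s) {
        args <- modifyList(config$scene_defaults,
                           c(gr$scene, list(rng_seed = s)))
        generate_scene(do.call(scene_spec, args))
      })
    }
    for (si in seq_along(scenes)) {
      res <- analyze_scene(scenes[[si]], config$mode,
                           preprocess = config$preprocess,
                           calling = config$calling)
      rows[[length(rows) + 1L]] <-
        data.frame(group = gname, sample = si, seed = seeds[si],
                   value = res$value)
      log_lines <- c(log_lines,
                     sprintf("group=%s sample=%d seed=%s value=%.6g",
                             gname, si, seeds[si], res$value))
    }
  }
  samples <- do.call(rbind, rows)
  data <- group_samples(samples$value, samples$group)
  report <- compare_groups(data, alpha = config$alpha)
  result <- structure(list(samples = samples, report = report,
                           config = config),
                      class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(samples, file.path(out_dir, "samples.csv"), row.names = FALSE)
    write.csv(report$summary, file.path(out_dir, "groups.csv"),
              row.names = FALSE)
    json <- list(mode = config$mode, alpha = config$alpha,
                 seed = config$seed,
                 value_column = value_name(config$mode),
                 omnibus = report$omnibus,
                 posthoc_method = report$method,
                 pairwise_p = as.data.frame(as.table(report$pairwise_p)),
                 letters = as.list(report$letters),
                 group_summary = report$summary)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  result
}

value_name <- function(mode) {
  switch(mode, viability = "viability_pct", calpastatin = "mean_au",
         "percent_positive")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> mode=%s, %d samples in %d groups\n",
              x$config$mode, nrow(x$samples),
              length(unique(x$samples$group))))
  print(x$report)
  invisible(x)
}
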