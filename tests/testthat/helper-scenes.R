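# Scene factories shared across test files.

# Small clean scene: no noise, no PSF, no mismatch; objects well separated.
clean_scene_spec <- function(n_cells = 12L, seed = 7L, ...) {
  args <- list(shape_voxels = c(40L, 128L, 128L),
               n_cells = n_cells,
               fraction_dead = 0.25,
               fraction_marker_positive = 0.4,
               psf_sigma_um = c(0, 0, 0),
               background_level = 0,
               shot_noise_scale = 0,
               read_noise_sd = 0,
               mismatch_shift_px = 0L,
               rng_seed = seed)
  do.call(scene_spec, utils::modifyList(args, list(...)))
}

# Realistic small scene: defaults (noise, PSF, mismatch) at reduced size.
noisy_scene_spec <- function(n_cells = 15L, seed = 11L, ...) {
  scene_spec(shape_voxels = c(48L, 160L, 160L), n_cells = n_cells,
             rng_seed = seed, ...)
}

# Match detected nuclei to ground-truth cells by nearest centroid.
match_objects_to_truth <- function(objects, truth) {
  vapply(seq_len(nrow(objects)), function(i) {
    d2 <- (truth$centroid_z - objects$centroid_z[i])^2 +
          (truth$centroid_y - objects$centroid_y[i])^2 +
          (truth$centroid_x - objects$centroid_x[i])^2
    which.min(d2)
  }, integer(1))
}

random_mask <- function(d, p, seed) {
  set.seed(seed)
  array(runif(prod(d)) < p, dim = d)
}
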