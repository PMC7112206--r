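disk_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx),
        function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("level set converges to a sharp-contrast disk from a smaller seed", {
  img <- matrix(10, 80, 80)
  img[disk_mask(80, 80, 40, 40, 20)] <- 100
  init <- disk_mask(80, 80, 40, 40, 8)
  out <- segment_cell_levelset(img, init)
  true_area <- pi * 20^2
  expect_lt(abs(sum(out) - true_area) / true_area, 0.1)
  expect_true(attr(out, "converged"))
  expect_false(attr(out, "degenerate"))
})

test_that("level set flags a contrast-free image as degenerate and keeps the seed", {
  img <- matrix(50, 40, 40)
  init <- disk_mask(40, 40, 20, 20, 6)
  out <- segment_cell_levelset(img, init)
  expect_true(attr(out, "degenerate"))
  expect_equal(as.vector(out), as.vector(init))
})

test_that("an exact two-phase cover is a fixed point of the evolution", {
  img <- matrix(5, 50, 50)
  fg <- disk_mask(50, 50, 25, 25, 12)
  img[fg] <- 90
  out <- segment_cell_levelset(img, fg)
  expect_identical(as.vector(out), as.vector(fg))
  expect_equal(attr(out, "iterations"), 1L)
})

test_that("level set rejects bad inputs", {
  img <- matrix(0, 10, 10)
  expect_error(segment_cell_levelset(img, matrix(FALSE, 10, 10)), "non-empty")
  expect_error(segment_cell_levelset(img, matrix(TRUE, 5, 5)), "matching")
})

test_that("3D cell mask is the outline extruded over the DAPI z-range", {
  d <- c(30, 40, 40)
  dapi <- array(FALSE, d)
  outline <- disk_mask(40, 40, 20, 20, 8)
  dapi[11:15, 18:22, 18:22] <- TRUE  # nucleus spanning z 11..15
  m <- build_cell_mask_3d(outline, dapi)
  expect_equal(m$provenance$z_range, c(11L, 15L))
  for (z in 11:15) expect_identical(m$voxels[z, , ], outline)
  expect_false(any(m$voxels[c(1:10, 16:30), , ]))
  # no overlapping DAPI -> empty mask with flag
  far <- array(FALSE, d); far[2:4, 2:4, 2:4] <- TRUE
  m2 <- build_cell_mask_3d(outline, far)
  expect_true(m2$provenance$empty)
  expect_false(any(m2$voxels))
  expect_error(build_cell_mask_3d(outline[1:10, ], dapi), "shape")
})

test_that("3D mask z-extent matches ground-truth nucleus extent within one slice", {
  sc <- generate_scene(clean_scene_spec(n_cells = 5L, seed = 29L))
  dapi <- preprocess_channel(sc$stacks$nuclei)
  tr <- sc$truth[1, ]
  outline <- disk_mask(dim(dapi$voxels)[2], dim(dapi$voxels)[3],
                       round(tr$centroid_y), round(tr$centroid_x),
                       tr$soma_radius_um / sc$spec$voxel_size_um[3])
  m <- build_cell_mask_3d(outline, dapi)
  r_vox <- tr$nucleus_radius_um / sc$spec$voxel_size_um[1]
  expect_lte(abs(m$provenance$z_range[1] - (tr$centroid_z - r_vox)), 1.5)
  expect_lte(abs(m$provenance$z_range[2] - (tr$centroid_z + r_vox)), 1.5)
})

test_that("AU saturates at 1 and gates everything at the noise floor to 0", {
  d <- c(10, 12, 12)
  maxI <- 255
  mask <- array(FALSE, d); mask[4:6, 4:6, 4:6] <- TRUE
  bg <- array(FALSE, d); bg[1:2, , ] <- TRUE
  a <- array(0, d); a[mask] <- maxI
  st <- channel_stack(a, c(1, 1, 1), 8L, "marker")
  res <- quantify_au(st, mask, bg)
  expect_equal(res$au, 1)
  expect_equal(res$n_voxels_included, 27L)

  flat <- channel_stack(array(40, d), c(1, 1, 1), 8L, "marker")
  res0 <- quantify_au(flat, mask, bg)
  expect_equal(res0$au, 0)
  expect_equal(res0$n_voxels_included, 0L)
})

test_that("AU equals an explicit-loop recomputation on a random scene", {
  set.seed(61)
  d <- c(8, 10, 10)
  a <- array(sample(0:255, prod(d), replace = TRUE), dim = d)
  mask <- array(FALSE, d); mask[3:6, 3:7, 3:7] <- TRUE
  bg <- array(FALSE, d); bg[1, , ] <- TRUE
  st <- channel_stack(a, c(1, 1, 1), 8L, "marker")
  res <- quantify_au(st, mask, bg)
  # oracle: explicit loop over voxels
  bgv <- c(); mv <- c()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (bg[z, y, x]) bgv <- c(bgv, a[z, y, x])
    if (mask[z, y, x]) mv <- c(mv, a[z, y, x])
  }
  floor_ <- mean(bgv); sd_ <- sd(bgv)
  inc <- mv[mv > floor_ + 2 * sd_]
  expect_equal(res$noise_floor, floor_)
  expect_equal(res$noise_sd, sd_)
  expect_equal(res$n_voxels_included, length(inc))
  expect_equal(res$au, mean(inc) / 255)
})

test_that("AU input contracts: empty or overlapping regions are rejected", {
  d <- c(4, 4, 4)
  st <- channel_stack(array(1, d), c(1, 1, 1), 8L, "marker")
  m <- array(FALSE, d); m[2, 2, 2] <- TRUE
  b <- array(FALSE, d); b[3, 3, 3] <- TRUE
  expect_error(quantify_au(st, array(FALSE, d), b), "empty cell mask")
  expect_error(quantify_au(st, m, array(FALSE, d)), "empty background")
  expect_error(quantify_au(st, m, m), "disjoint")
})

test_that("AU is monotone in mask intensity and blind to sub-gate voxels", {
  set.seed(67)
  d <- c(6, 8, 8)
  a <- array(round(runif(prod(d), 20, 30)), dim = d)
  mask <- array(FALSE, d); mask[3:4, 3:6, 3:6] <- TRUE
  a[mask] <- round(runif(sum(mask), 150, 220))
  bg <- array(FALSE, d); bg[1, , ] <- TRUE
  st1 <- channel_stack(a, c(1, 1, 1), 8L, "marker")
  res1 <- quantify_au(st1, mask, bg)
  # pointwise increase inside the mask cannot lower AU
  a2 <- a; a2[mask] <- pmin(a2[mask] + 10, 255)
  res2 <- quantify_au(channel_stack(a2, c(1, 1, 1), 8L, "marker"), mask, bg)
  expect_gte(res2$au, res1$au)
  # adding sub-gate voxels to the mask leaves AU unchanged
  mask_big <- mask; mask_big[6, 7:8, 7:8] <- TRUE  # background-level voxels
  res3 <- quantify_au(st1, mask_big, bg)
  expect_equal(res3$au, res1$au)
})

test_that("synthetic high/medium/low marker scenes give strictly ordered AU", {
  au_for <- function(lohi, seed) {
    sc <- generate_scene(scene_spec(
      shape_voxels = c(40L, 128L, 128L), n_cells = 6L, fraction_dead = 0,
      fraction_marker_positive = 1, marker_intensity_range = lohi,
      rng_seed = seed))
    analyze_scene(sc, "calpastatin")$value
  }
  au_hi <- au_for(c(0.80, 0.90), 71)
  au_md <- au_for(c(0.45, 0.55), 71)
  au_lo <- au_for(c(0.15, 0.25), 71)
  expect_gt(au_hi, au_md)
  expect_gt(au_md, au_lo)
})
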