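make_bbox <- function(z0, z1, y0, y1, x0, x1) {
  list(z0 = z0, z1 = z1, y0 = y0, y1 = y1, x0 = x0, x1 = x1)
}

test_that("object detection finds spheres with sensible extent and empty masks give empty tables", {
  expect_equal(nrow(detect_objects(array(FALSE, c(4, 4, 4)))), 0L)

  a <- array(FALSE, c(24, 24, 24))
  ctr <- c(12, 12, 12)
  for (z in 1:24) for (y in 1:24) for (x in 1:24)
    if (sum((c(z, y, x) - ctr)^2) <= 64) a[z, y, x] <- TRUE
  objs <- detect_objects(a, min_voxels = 10L)
  expect_equal(nrow(objs), 1L)
  expect_gte(objs$extent_ratio, 0.4)
  expect_lte(objs$extent_ratio, 0.7)
  # direct recomputation of the extent ratio
  expect_equal(objs$extent_ratio,
               objs$voxel_count / ((objs$z1 - objs$z0) *
                                   (objs$y1 - objs$y0) * (objs$x1 - objs$x0)))
  # centroid lies inside the half-open bbox
  expect_true(objs$centroid_z >= objs$z0 && objs$centroid_z < objs$z1)
})

test_that("a filament passes the extent screen but the elongation cap rejects it", {
  a <- array(FALSE, c(50, 8, 8))
  a[4:43, 4, 4] <- TRUE  # 1x1x40 filament: extent ratio 1.0
  expect_equal(nrow(detect_objects(a, min_voxels = 10L)), 1L)
  expect_equal(nrow(detect_objects(a, min_voxels = 10L, max_elongation = 3)),
               0L)
})

test_that("bbox overlap uses half-open intervals: shared faces do not overlap", {
  a <- make_bbox(1, 5, 1, 5, 1, 5)
  expect_true(bboxes_overlap(a, a))
  b <- make_bbox(1, 5, 1, 5, 5, 9)  # shares the face x = 5
  expect_false(bboxes_overlap(a, b))
  expect_false(bboxes_overlap(b, a))
  c <- make_bbox(4, 6, 4, 6, 4, 6)
  expect_true(bboxes_overlap(a, c))
})

test_that("bbox overlap agrees with the voxel-set intersection oracle on 1000 random pairs", {
  set.seed(53)
  mismatches <- 0L
  for (i in 1:1000) {
    rb <- function() {
      lo <- sample(1:8, 3, replace = TRUE)
      len <- sample(1:5, 3, replace = TRUE)
      make_bbox(lo[1], lo[1] + len[1], lo[2], lo[2] + len[2],
                lo[3], lo[3] + len[3])
    }
    a <- rb(); b <- rb()
    if (bboxes_overlap(a, b) != oracle_boxes_intersect(a, b))
      mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("objects from stacks of different shapes cannot be compared", {
  a <- structure(make_bbox(1, 3, 1, 3, 1, 3), stack_dim = c(10L, 10L, 10L))
  b <- structure(make_bbox(1, 3, 1, 3, 1, 3), stack_dim = c(12L, 10L, 10L))
  expect_error(bboxes_overlap(a, b), "different shape")
})

test_that("the exclusion rule: dead wins over marker; positivity needs a marker overlap", {
  obj_row <- function(id, lo, hi) {
    data.frame(object_id = id, z0 = lo, z1 = hi, y0 = lo, y1 = hi,
               x0 = lo, x1 = hi,
               centroid_z = (lo + hi) / 2, centroid_y = (lo + hi) / 2,
               centroid_x = (lo + hi) / 2,
               voxel_count = (hi - lo)^3, extent_ratio = 1)
  }
  nuclei <- rbind(obj_row(1, 1, 4), obj_row(2, 10, 14))
  dead <- obj_row(1, 2, 5)       # overlaps nucleus 1
  markers <- obj_row(1, 1, 12)   # overlaps both nuclei
  calls <- call_cells(nuclei, dead, markers)
  expect_equal(calls$is_dead, c(TRUE, FALSE))
  expect_equal(calls$is_marker_positive, c(FALSE, TRUE))
  # no markers at all -> zero positives
  calls0 <- call_cells(nuclei, dead, markers[0, ])
  expect_false(any(calls0$is_marker_positive))
  # percent positive: 1 positive of 1 live nucleus
  expect_equal(percent_positive(calls), 100)
  expect_equal(percent_positive(calls, denominator = "all"), 50)
})

test_that("percent_positive equals a brute-force recount and handles edge cases", {
  tab <- data.frame(nucleus_id = 1:10,
                    is_dead = rep(c(TRUE, FALSE), c(2, 8)),
                    is_marker_positive = rep(c(FALSE, TRUE, FALSE), c(2, 3, 5)))
  expect_equal(percent_positive(tab), 100 * 3 / 8)
  expect_equal(percent_positive(tab),
               100 * sum(tab$is_marker_positive & !tab$is_dead) /
                 sum(!tab$is_dead))
  all_dead <- data.frame(nucleus_id = 1, is_dead = TRUE,
                         is_marker_positive = FALSE)
  expect_error(percent_positive(all_dead), "no live")
})

test_that("viability arithmetic and degenerate inputs", {
  live <- detect_objects(array(FALSE, c(2, 2, 2)))
  dead <- live
  expect_error(viability(live, dead), "no objects")

  obj <- function(n, offset = 0) {
    if (n == 0) return(structure(data.frame(), stack_dim = c(50L, 50L, 50L)))
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      lo <- offset + i * 6
      data.frame(object_id = i, z0 = lo, z1 = lo + 3, y0 = 1, y1 = 4,
                 x0 = 1, x1 = 4, centroid_z = lo + 1, centroid_y = 2,
                 centroid_x = 2, voxel_count = 27, extent_ratio = 1)
    }))
    structure(df, stack_dim = c(200L, 50L, 50L))
  }
  v <- viability(obj(10), obj(0))
  expect_equal(v$viability_pct, 100)
  v2 <- viability(obj(0), obj(5))
  expect_equal(v2$viability_pct, 0)
  v3 <- viability(obj(6), obj(2, offset = 100))
  expect_equal(v3$n_live, 6)
  expect_equal(v3$n_dead, 2)
  expect_equal(v3$viability_pct, 75)
})

test_that("calls on a clean well-separated scene match ground truth exactly", {
  sc <- generate_scene(clean_scene_spec(n_cells = 12L, seed = 17L))
  masks <- lapply(c("nuclei", "dead", "marker"), function(role)
    preprocess_channel(sc$stacks[[role]]))
  objs <- lapply(masks, detect_objects)
  nuclei <- objs[[1]]
  expect_equal(nrow(nuclei), 12L)
  calls <- call_cells(nuclei, objs[[2]], objs[[3]])
  m <- match_objects_to_truth(nuclei, sc$truth)
  expect_equal(calls$is_dead, sc$truth$is_dead[m])
  expect_equal(calls$is_marker_positive, sc$truth$is_marker_positive[m])
  # live/dead viability also exact
  live_objs <- detect_objects(preprocess_channel(sc$stacks$live))
  v <- viability(live_objs, objs[[2]])
  expect_equal(v$viability_pct, 100 * sum(!sc$truth$is_dead) / 12)
})

test_that("calls are invariant under a global translation of all channels", {
  sc <- generate_scene(clean_scene_spec(n_cells = 8L, seed = 19L))
  shift_all <- function(a, dz, dy, dx) {
    d <- dim(a)
    out <- array(0, d)
    out[(1 + dz):d[1], (1 + dy):d[2], (1 + dx):d[3]] <-
      a[1:(d[1] - dz), 1:(d[2] - dy), 1:(d[3] - dx)]
    out
  }
  get_calls <- function(stacks) {
    objs <- lapply(stacks, function(a) detect_objects(a > 0))
    call_cells(objs[[1]], objs[[2]], objs[[3]])
  }
  raw <- lapply(c("nuclei", "dead", "marker"),
                function(r) sc$stacks[[r]]$voxels)
  shifted <- lapply(raw, shift_all, dz = 2, dy = 3, dx = 1)
  c1 <- get_calls(raw)
  c2 <- get_calls(shifted)
  expect_equal(c1$is_dead, c2$is_dead)
  expect_equal(c1$is_marker_positive, c2$is_marker_positive)
})

test_that("percent_positive and viability are permutation-invariant in object order", {
  sc <- generate_scene(clean_scene_spec(n_cells = 10L, seed = 23L))
  nuclei <- detect_objects(preprocess_channel(sc$stacks$nuclei))
  dead <- detect_objects(preprocess_channel(sc$stacks$dead))
  markers <- detect_objects(preprocess_channel(sc$stacks$marker))
  set.seed(1)
  perm <- function(df) df[sample(nrow(df)), , drop = FALSE]
  p1 <- percent_positive(call_cells(nuclei, dead, markers))
  p2 <- percent_positive(call_cells(perm(nuclei), perm(dead), perm(markers)))
  expect_equal(p1, p2)
  live <- detect_objects(preprocess_channel(sc$stacks$live))
  expect_equal(viability(live, dead)$viability_pct,
               viability(perm(live), perm(dead))$viability_pct)
})
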