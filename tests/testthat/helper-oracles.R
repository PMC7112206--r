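# Independent brute-force oracles used to check the package's fast paths.
# They deliberately share no code with the implementation.

# 3D connected components by breadth-first flood fill over coordinate triples.
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  man <- rowSums(abs(offs))
  offs <- offs[man <= switch(as.character(connectivity),
                             "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  labels <- array(0L, d)
  nl <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    nl <- nl + 1L
    queue <- list(arrayInd(start, d)[1, ])
    labels[start] <- nl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- nl
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  labels
}

# Exhaustive Otsu: try every threshold, compute between-class variance
# directly from the raw values; ties resolved by the plateau midpoint.
oracle_otsu <- function(values, max_intensity) {
  n <- length(values)
  bcv <- rep(-Inf, max_intensity + 1)
  for (t in 0:max_intensity) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    bcv[t + 1] <- (length(lo) / n) * (length(hi) / n) *
      (mean(lo) - mean(hi))^2
  }
  best <- max(bcv)
  mean((0:max_intensity)[abs(bcv - best) <= 1e-9 * best])
}

# Brute-force 3D median filter with edge replication.
oracle_median3d <- function(a, radius) {
  d <- dim(a)
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    zs <- pmin(pmax((z - radius):(z + radius), 1), d[1])
    ys <- pmin(pmax((y - radius):(y + radius), 1), d[2])
    xs <- pmin(pmax((x - radius):(x + radius), 1), d[3])
    v <- sort(as.numeric(a[zs, ys, xs]))
    out[z, y, x] <- v[(length(v) + 1) / 2]
  }
  out
}

# Voxel-set intersection of two filled half-open boxes.
oracle_boxes_intersect <- function(a, b) {
  vox <- function(bb) {
    g <- expand.grid(z = bb$z0:(bb$z1 - 1), y = bb$y0:(bb$y1 - 1),
                     x = bb$x0:(bb$x1 - 1))
    paste(g$z, g$y, g$x)
  }
  length(intersect(vox(a), vox(b))) > 0
}

# Tie-corrected Kruskal-Wallis H from the textbook rank formula.
oracle_kw_h <- function(values, group) {
  N <- length(values)
  rk <- rank(values)
  groups <- split(rk, group)
  h <- 12 / (N * (N + 1)) *
    sum(vapply(groups, function(r) length(r) * (mean(r) - (N + 1) / 2)^2,
               numeric(1)))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Explicit finite-difference solution of the axisymmetric heat equation on
# an (r, z) grid, Dirichlet surfaces, uniform unit initial excess.
# Returns the dimensionless excess field at t_end.
oracle_fd_cylinder <- function(spec, t_end, nr = 101, nz = 101) {
  R <- spec$radius_m; H <- spec$height_m; al <- spec$diffusivity_m2s
  dr <- R / (nr - 1); dz <- H / (nz - 1)
  dt <- 0.2 / (al * (2 / dr^2 + 2 / dz^2))
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  th <- matrix(1, nr, nz)
  r <- seq(0, R, length.out = nr)
  th[nr, ] <- 0; th[, 1] <- 0; th[, nz] <- 0
  ii <- 2:(nr - 1); jj <- 2:(nz - 1)
  rinv <- 1 / r[ii]
  for (s in seq_len(nsteps)) {
    lap <- matrix(0, nr, nz)
    lap[ii, jj] <-
      (th[ii + 1, jj] - 2 * th[ii, jj] + th[ii - 1, jj]) / dr^2 +
      (th[ii + 1, jj] - th[ii - 1, jj]) / (2 * dr) * rinv +
      (th[ii, jj + 1] - 2 * th[ii, jj] + th[ii, jj - 1]) / dz^2
    # axis r = 0: (1/r) d/dr(r dT/dr) -> 4 (T(dr) - T(0)) / dr^2
    lap[1, jj] <- 4 * (th[2, jj] - th[1, jj]) / dr^2 +
      (th[1, jj + 1] - 2 * th[1, jj] + th[1, jj - 1]) / dz^2
    th <- th + al * dt * lap
    th[nr, ] <- 0; th[, 1] <- 0; th[, nz] <- 0
  }
  th
}
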