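# Independent brute-force oracles used across the suite. All are O(n^2)-ish
# and meant for grids of <= 32^3 voxels; they deliberately avoid the
# package's distance-transform and gamma code paths.

# Cube grid of n voxels per axis centered on the origin.
cube_grid <- function(n, spacing = 1) {
  voxel_grid(rep(-(n - 1) / 2 * spacing, 3), spacing, rep(n, 3))
}

# n x 3 matrix of all voxel-center world coordinates.
all_centers <- function(grid) {
  idx <- as.matrix(expand.grid(i = 0:(grid$dims[1] - 1),
                               j = 0:(grid$dims[2] - 1),
                               k = 0:(grid$dims[3] - 1)))
  sweep(sweep(idx, 2, grid$spacing_mm, `*`), 2, grid$origin_mm, `+`)
}

# Exhaustive distance (mm) from every voxel center to the nearest center in
# the target set; Inf when the target set is empty.
bf_distance_to_set <- function(grid, target_logical) {
  pts <- all_centers(grid)
  tgt <- pts[as.vector(target_logical), , drop = FALSE]
  if (nrow(tgt) == 0L) return(array(Inf, grid$dims))
  d2 <- matrix(Inf, nrow(pts), 1)
  dmin <- rep(Inf, nrow(pts))
  for (t in seq_len(nrow(tgt))) {
    dt <- (pts[, 1] - tgt[t, 1])^2 + (pts[, 2] - tgt[t, 2])^2 +
      (pts[, 3] - tgt[t, 3])^2
    dmin <- pmin(dmin, dt)
  }
  array(sqrt(dmin), grid$dims)
}

bf_expand <- function(mask, margin) {
  d <- bf_distance_to_set(mask$grid, mask$occupancy)
  structure_mask(mask$grid, d <= margin, mask$name, mask$role)
}

bf_retract <- function(mask, margin) {
  d <- bf_distance_to_set(mask$grid, !mask$occupancy)
  structure_mask(mask$grid, mask$occupancy & d > margin,
                 mask$name, mask$role)
}

# All-pairs mean surface distance between boundary voxel sets, where the
# boundary is recomputed here with a naive 6-neighbour scan.
bf_boundary <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!occ[i, j, k]) next
    nb <- c(if (i > 1) occ[i - 1, j, k] else FALSE,
            if (i < d[1]) occ[i + 1, j, k] else FALSE,
            if (j > 1) occ[i, j - 1, k] else FALSE,
            if (j < d[2]) occ[i, j + 1, k] else FALSE,
            if (k > 1) occ[i, j, k - 1] else FALSE,
            if (k < d[3]) occ[i, j, k + 1] else FALSE)
    if (!all(nb)) out[i, j, k] <- TRUE
  }
  out
}

bf_msd <- function(a, b) {
  pts <- all_centers(a$grid)
  sa <- pts[as.vector(bf_boundary(a)), , drop = FALSE]
  sb <- pts[as.vector(bf_boundary(b)), , drop = FALSE]
  dmat <- outer(rowSums(sa^2), rowSums(sb^2), `+`) - 2 * sa %*% t(sb)
  dmat[dmat < 0] <- 0
  dmat <- sqrt(dmat)
  (mean(apply(dmat, 1, min)) + mean(apply(dmat, 2, min))) / 2
}

# Exhaustive gamma: every reference voxel against every evaluated voxel
# center within the search radius (no interpolation).
bf_gamma_pass_rate <- function(ref, ev, dose_diff_pct, dta_mm,
                               threshold_pct, search_radius_mm) {
  dmax <- max(ref$dose_gy)
  dd <- dose_diff_pct / 100 * dmax
  thr <- threshold_pct / 100 * dmax
  rp <- all_centers(ref$grid)
  ep <- all_centers(ev$grid)
  rd <- as.vector(ref$dose_gy)
  ed <- as.vector(ev$dose_gy)
  keep <- rd >= thr
  g <- rep(NA_real_, length(rd))
  for (i in which(keep)) {
    dr2 <- (ep[, 1] - rp[i, 1])^2 + (ep[, 2] - rp[i, 2])^2 +
      (ep[, 3] - rp[i, 3])^2
    ok <- dr2 <= search_radius_mm^2
    if (!any(ok)) next
    g2 <- dr2[ok] / dta_mm^2 + ((rd[i] - ed[ok]) / dd)^2
    g[i] <- sqrt(min(g2))
  }
  vals <- g[!is.na(g)]
  list(pass_rate = 100 * mean(vals <= 1), gamma = g)
}

# Seeded random blob: union of a few random balls, guaranteed non-empty.
random_blob <- function(grid, seed, n_balls = 3, r_range = c(3, 6)) {
  set.seed(seed)
  occ <- array(FALSE, grid$dims)
  b <- grid_bounds_mm(grid)
  span <- (b["hi", ] - b["lo", ]) / 4
  for (s in seq_len(n_balls)) {
    ctr <- runif(3, -span, span)
    r <- runif(1, r_range[1], r_range[2])
    m <- suppressWarnings(voxelize_solid(solid_sphere(ctr, r), grid))
    occ <- occ | m$occupancy
  }
  occ[(grid$dims[1] + 1) %/% 2, (grid$dims[2] + 1) %/% 2,
      (grid$dims[3] + 1) %/% 2] <- TRUE
  structure_mask(grid, occ, "blob", "GTV")
}

# Flood fill from one occupied voxel; returns number of reached voxels
# (6-connectivity), for connectedness checks.
flood_fill_count <- function(occ) {
  d <- dim(occ)
  idx <- which(occ)
  if (length(idx) == 0L) return(0L)
  visited <- logical(length(occ))
  frontier <- idx[1]
  visited[frontier] <- TRUE
  nx <- d[1]; nxy <- d[1] * d[2]
  repeat {
    nbrs <- c(frontier - 1, frontier + 1, frontier - nx, frontier + nx,
              frontier - nxy, frontier + nxy)
    # drop neighbours that wrapped across a face
    ai <- arrayInd(frontier, d)
    keep <- c(ai[, 1] > 1, ai[, 1] < d[1], ai[, 2] > 1, ai[, 2] < d[2],
              ai[, 3] > 1, ai[, 3] < d[3])
    nbrs <- nbrs[keep]
    nbrs <- unique(nbrs[nbrs >= 1 & nbrs <= length(occ)])
    nbrs <- nbrs[occ[nbrs] & !visited[nbrs]]
    if (length(nbrs) == 0L) break
    visited[nbrs] <- TRUE
    frontier <- nbrs
  }
  sum(visited)
}

# Small planning scene reused by painter/DVH tests: spherical GTV inside a
# generous body on a 2 mm grid, with the default lattice cropped to it.
small_scene <- function(gtv_r = 30, n = 41, spacing = 2) {
  grid <- cube_grid(n, spacing)
  body <- structure_mask(grid, array(TRUE, grid$dims), "Body", "Body")
  gtv <- voxelize_solid(solid_sphere(c(0, 0, 0), gtv_r), grid, "GTV", "GTV")
  spheres <- generate_lattice(lattice_spec(matrix_extent_mm = 100))
  structures <- suppressWarnings(derive_structures(gtv, body, spheres))
  structures
}
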