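#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` over occupied voxels of two masks on one grid.
#' Two empty masks are defined as identical (Dice 1), the identity
#' convention.
#'
#' @param a,b [structure_mask()] objects on identical grids.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  na <- sum(a$occupancy); nb <- sum(b$occupancy)
  if (na + nb == 0L) return(1)
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

# Boundary voxels: occupied with at least one 6-neighbour unoccupied
# (out-of-grid counts as unoccupied).
boundary_voxels <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  interior <- array(TRUE, d)
  shift_all <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      occ[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    if (d[ax] == 1L) { interior[] <- FALSE; next }
    interior <- interior & shift_all(ax, by)
  }
  occ & !interior
}

#' Mean surface distance between two masks
#'
#' Symmetric mean of nearest-surface distances (mm) between the boundary
#' voxel sets of the two masks: the average of the two directed mean
#' distances. Surface voxels are occupied voxels with an unoccupied
#' 6-neighbour. Distances are exact Euclidean distances between voxel
#' centers.
#'
#' @param a,b Non-empty [structure_mask()] objects on identical grids.
#' @return Mean surface distance in mm.
#' @export
mean_surface_distance <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  if (is_empty_mask(a) || is_empty_mask(b))
    stop("mean surface distance requires two non-empty masks")
  sa <- boundary_voxels(a); sb <- boundary_voxels(b)
  da_to_b <- sqrt(edt_sq_cpp(as.logical(sb), a$grid$dims, a$grid$spacing_mm))
  db_to_a <- sqrt(edt_sq_cpp(as.logical(sa), a$grid$dims, a$grid$spacing_mm))
  (mean(da_to_b[sa]) + mean(db_to_a[sb])) / 2
}
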