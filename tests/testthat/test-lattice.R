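# Counting oracle: integer offsets o with |o| * spacing <= extent / 2.
count_planes <- function(extent, spacing) {
  sum(abs(-20:20) * spacing <= extent / 2 + 1e-9)
}

test_that("lattice generation reproduces the default sphere matrix", {
  spheres <- generate_lattice(lattice_spec())
  expect_equal(n_spheres(spheres), count_planes(200, 20)^3)
  expect_equal(n_spheres(spheres), 1331L)
  small <- generate_lattice(lattice_spec(matrix_extent_mm = 20))
  expect_equal(n_spheres(small), 27L)
  # minimum pairwise center distance is exactly the 20 mm spacing
  cm <- as.matrix(small$centers_mm)
  dmin <- min(dist(cm))
  expect_identical(dmin, 20)
  expect_equal(2 * spheres$radius_mm, 10)
  expect_error(lattice_spec(center_spacing_mm = 8), "overlap")
})

test_that("lattice centers honour an off-origin center point", {
  sp <- generate_lattice(lattice_spec(matrix_extent_mm = 40,
                                      center_point_mm = c(3, -7, 11)))
  cm <- as.matrix(sp$centers_mm)
  expect_true(all(abs(sweep(cm, 2, c(3, -7, 11)) %% 20) < 1e-9))
  expect_equal(colMeans(cm), c(3, -7, 11), ignore_attr = TRUE)
})

test_that("voxelized lattice is the union of per-sphere voxelizations", {
  g <- cube_grid(53, 1)
  sp <- generate_lattice(lattice_spec(matrix_extent_mm = 20))
  m <- voxelize_lattice(sp, g)
  # disjoint spheres: additive volume
  expect_lt(abs(volume_cc(m) - 27 * 4 / 3 * pi * 0.5^3) /
              (27 * 4 / 3 * pi * 0.5^3), 0.05)
  oracle <- array(FALSE, g$dims)
  for (i in seq_len(n_spheres(sp))) {
    s <- voxelize_solid(solid_sphere(as.numeric(sp$centers_mm[i, ]),
                                     sp$radius_mm), g)
    oracle <- oracle | s$occupancy
  }
  expect_identical(m$occupancy, oracle)
  empty <- generate_lattice(lattice_spec(matrix_extent_mm = 20))
  empty$centers_mm <- empty$centers_mm[0, ]
  expect_true(is_empty_mask(voxelize_lattice(empty, g)))
})

test_that("cropping keeps only spheres wholly inside the retracted GTV", {
  g <- cube_grid(111, 2)
  spheres <- generate_lattice(lattice_spec())
  gtv <- voxelize_solid(solid_sphere(c(0, 0, 0), 30), g, "GTV", "GTV")
  crop <- crop_to_ptv_high(spheres, gtv)
  # neighbours at 20 mm exceed the 15 mm allowable center distance
  expect_equal(n_spheres(crop$kept), 1L)
  expect_equal(as.numeric(crop$kept$centers_mm[1, ]), c(0, 0, 0))

  gtv65 <- voxelize_solid(solid_sphere(c(0, 0, 0), 65), g, "GTV", "GTV")
  crop65 <- crop_to_ptv_high(spheres, gtv65)
  # analytic criterion ||c|| <= 65 - 10 - 5, within one voxel at the boundary
  cn <- sqrt(rowSums(as.matrix(crop65$kept$centers_mm)^2))
  vox <- sqrt(sum(g$spacing_mm^2))
  expect_true(all(cn <= 50 + vox))
  rn <- sqrt(rowSums(as.matrix(crop65$removed$centers_mm)^2))
  expect_true(all(rn >= 50 - vox))
  all_n <- sqrt(rowSums(as.matrix(spheres$centers_mm)^2))
  expect_gte(n_spheres(crop65$kept), sum(all_n <= 50 - vox))
  expect_lte(n_spheres(crop65$kept), sum(all_n <= 50 + vox))
  # every kept-sphere voxel is a GTV voxel
  expect_true(all(gtv65$occupancy[crop65$ptv_high$occupancy]))
})

test_that("cropping is monotone in GTV size and retraction", {
  g <- cube_grid(101, 2)
  spheres <- generate_lattice(lattice_spec(matrix_extent_mm = 100))
  small <- voxelize_solid(solid_sphere(c(0, 0, 0), 35), g, "GTV", "GTV")
  large <- voxelize_solid(solid_sphere(c(0, 0, 0), 55), g, "GTV", "GTV")
  k_small <- n_spheres(crop_to_ptv_high(spheres, small)$kept)
  k_large <- n_spheres(crop_to_ptv_high(spheres, large)$kept)
  expect_gte(k_large, k_small)
  k_more_retract <- n_spheres(
    crop_to_ptv_high(spheres, large, retraction_mm = 20)$kept)
  expect_lte(k_more_retract, k_large)
  # rerun is bit-identical (no randomness anywhere)
  c1 <- crop_to_ptv_high(spheres, large)
  c2 <- crop_to_ptv_high(spheres, large)
  expect_identical(c1$ptv_high$occupancy, c2$ptv_high$occupancy)
})

test_that("a GTV outside the matrix removes every sphere", {
  g <- voxel_grid(c(180, -20, -20), 2, c(21, 21, 21))
  gtv <- voxelize_solid(solid_sphere(c(200, 0, 0), 15), g, "GTV", "GTV")
  spheres <- generate_lattice(lattice_spec(matrix_extent_mm = 100))
  expect_warning(crop <- crop_to_ptv_high(spheres, gtv), "no sphere")
  expect_true(is_empty_mask(crop$ptv_high))
  expect_equal(n_spheres(crop$kept), 0L)
})
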