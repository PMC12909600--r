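test_that("voxel grid validates geometry and computes derived quantities", {
  g <- voxel_grid(c(-10, -10, -10), c(1, 2, 4), c(21, 11, 6))
  expect_equal(voxel_volume_cc(g), 8 / 1000)
  expect_equal(grid_axis_mm(g, 2), seq(-10, 10, by = 2))
  expect_error(voxel_grid(c(0, 0, 0), c(1, -1, 1), c(4, 4, 4)), "positive")
  expect_error(voxel_grid(c(0, 0, 0), 1, c(4, 0, 4)), "positive integers")
  expect_true(same_grid(g, voxel_grid(c(-10, -10, -10), c(1, 2, 4),
                                      c(21, 11, 6))))
  expect_false(same_grid(g, cube_grid(5)))
})

test_that("mask volume is invariant under axis permutation", {
  g <- cube_grid(16, 2)
  m <- random_blob(g, seed = 4)
  vol <- volume_cc(m)
  perm <- structure_mask(voxel_grid(g$origin_mm[c(3, 1, 2)],
                                    g$spacing_mm[c(3, 1, 2)],
                                    g$dims[c(3, 1, 2)]),
                         aperm(m$occupancy, c(3, 1, 2)))
  expect_equal(volume_cc(perm), vol)
})

test_that("voxelize_solid uses voxel-center inclusion", {
  g <- cube_grid(31, 1)
  s <- voxelize_solid(solid_sphere(c(0, 0, 0), 5), g)
  expect_lt(abs(volume_cc(s) - 4 / 3 * pi * 0.5^3) / (4 / 3 * pi * 0.5^3),
            0.05)
  expect_warning(z <- voxelize_solid(solid_sphere(c(0, 0, 0), 0), g),
                 "empty")
  expect_equal(volume_cc(z), 0)
  # ellipsoid vs exhaustive center-inclusion count
  g2 <- cube_grid(45, 1)
  e <- voxelize_solid(solid_ellipsoid(c(0, 0, 0), c(20, 15, 10)), g2)
  pts <- all_centers(g2)
  n_inside <- sum((pts[, 1] / 20)^2 + (pts[, 2] / 15)^2 +
                    (pts[, 3] / 10)^2 <= 1)
  expect_equal(sum(e$occupancy), n_inside)
  # solid entirely off-grid warns, does not fail
  expect_warning(off <- voxelize_solid(solid_sphere(c(500, 0, 0), 5), g),
                 "empty")
  expect_true(is_empty_mask(off))
})

test_that("mask and dose I/O round-trips preserve data and geometry", {
  tmp <- withr::local_tempdir()
  g <- voxel_grid(c(-31, -31, -31), 2, c(32, 32, 32))
  set.seed(7)
  m <- structure_mask(g, array(runif(32^3) > 0.5, g$dims), "GTV", "GTV")
  p <- file.path(tmp, "m.nii.gz")
  write_mask(m, p)
  m2 <- read_mask(p, "GTV", "GTV")
  expect_identical(m2$occupancy, m$occupancy)
  expect_true(same_grid(m$grid, m2$grid))

  d <- dose_grid(g, array(runif(32^3, 0, 15), g$dims))
  pd <- file.path(tmp, "d.nii.gz")
  write_dose(d, pd)
  d2 <- read_dose(pd)
  expect_lt(max(abs(d2$dose_gy - d$dose_gy)), 1e-6)
})

test_that("non-axis-aligned orientation is rejected on read", {
  tmp <- withr::local_tempdir()
  arr <- array(runif(27), c(3, 3, 3))
  img <- RNifti::asNifti(arr)
  th <- pi / 7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xf <- rbind(cbind(2 * rot, c(0, 0, 0)), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  p <- file.path(tmp, "rot.nii.gz")
  RNifti::writeNifti(img, p)
  expect_error(read_dose(p), "orientation")
})

test_that("case manifests round-trip and enforce a common grid", {
  tmp <- withr::local_tempdir()
  case <- generate_case(case_spec("extremity", "ellipsoid", c(45, 45, 60),
                                  seed = 3))
  man <- write_case(case, file.path(tmp, "case"))
  back <- read_case(file.path(tmp, "case", "manifest.json"))
  expect_identical(back$case_id, case$case_id)
  expect_identical(back$masks$GTV$occupancy, case$masks$GTV$occupancy)
  expect_setequal(back$manifest$name, names(case$masks))

  # corrupt one mask onto a shifted grid -> geometry-mismatch error
  g2 <- voxel_grid(case$grid$origin_mm + 1, case$grid$spacing_mm,
                   case$grid$dims)
  bad <- structure_mask(g2, case$masks$GTV$occupancy, "GTV", "GTV")
  write_mask(bad, file.path(tmp, "case", "GTV.nii.gz"))
  expect_error(read_case(file.path(tmp, "case", "manifest.json")),
               "geometry mismatch")
})
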