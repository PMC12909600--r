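uniform_scene <- function(value_gy = 10, n = 12, spacing = 2) {
  g <- cube_grid(n, spacing)
  mask <- structure_mask(g, array(TRUE, g$dims), "S", "PTV_Low")
  list(dose = dose_grid(g, array(value_gy, g$dims)), mask = mask, grid = g)
}

test_that("dose-at-volume reproduces step distributions", {
  u <- uniform_scene(10)
  expect_equal(dose_at_volume(u$dose, u$mask, volume_cc = 0.03), 10)
  # 1 cc at 15 Gy on top of 99 cc at 4 Gy (2 mm voxels: 0.008 cc each)
  g <- voxel_grid(c(0, 0, 0), 2, c(25, 25, 20))
  vals <- rep(4, prod(c(25, 25, 20)))
  vals[1:125] <- 15
  d <- dose_grid(g, array(vals, c(25, 25, 20)))
  m <- structure_mask(g, array(TRUE, c(25, 25, 20)), "S", "PTV_Low")
  expect_equal(dose_at_volume(d, m, volume_cc = 0.03), 15)
  expect_equal(dose_at_volume(d, m, volume_pct = 95), 4)
  expect_error(dose_at_volume(d, m, volume_cc = 1e5), "exceeds")
  expect_error(dose_at_volume(d, m), "exactly one")
})

test_that("DVH metrics agree with exhaustive sort and count oracles", {
  g <- cube_grid(14, 2)
  set.seed(5)
  d <- dose_grid(g, array(runif(prod(g$dims), 0, 16), g$dims))
  m <- random_blob(g, 9)
  ds <- sort(d$dose_gy[m$occupancy], decreasing = TRUE)
  vv <- voxel_volume_cc(g)
  for (v_cc in c(0.03, 0.1, 0.4)) {
    got <- dose_at_volume(d, m, volume_cc = v_cc)
    k <- max(ceiling(v_cc / vv), 1)
    # interpolated value lies between the bracketing sorted voxel doses
    expect_lte(got, ds[max(floor(v_cc / vv), 1)] + 1e-12)
    expect_gte(got, ds[min(k + 1, length(ds))] - 1e-12)
  }
  for (thr in c(2, 8, 14)) {
    expect_equal(volume_at_dose(d, m, thr),
                 100 * sum(d$dose_gy[m$occupancy] >= thr) / sum(m$occupancy))
    expect_equal(volume_at_dose(d, m, thr, mode = "cc"),
                 sum(d$dose_gy[m$occupancy] >= thr) * vv)
  }
  expect_equal(mean_dose(d, m),
               sum(d$dose_gy[m$occupancy]) / sum(m$occupancy))
})

test_that("volume-at-dose handles uniform and split distributions", {
  u <- uniform_scene(12)
  expect_equal(volume_at_dose(u$dose, u$mask, 12), 100)
  half <- u$dose$dose_gy
  half[seq_len(length(half) / 2)] <- 4
  d <- dose_grid(u$grid, half)
  expect_equal(volume_at_dose(d, u$mask, 12), 50)
})

test_that("DVH curves are monotone and anchored at 100% coverage", {
  g <- cube_grid(14, 2)
  set.seed(8)
  d <- dose_grid(g, array(rgamma(prod(g$dims), 4, 1), g$dims))
  m <- random_blob(g, 10)
  curve <- dvh_curve(d, m)
  expect_equal(curve$volume_pct[1], 100)
  expect_true(all(diff(curve$volume_pct) <= 0))
  expect_equal(curve$volume_cc, curve$volume_pct / 100 * volume_cc(m))
})

test_that("dose/volume lookups satisfy the Galois consistency bound", {
  g <- cube_grid(14, 2)
  set.seed(15)
  d <- dose_grid(g, array(runif(prod(g$dims), 0, 16), g$dims))
  m <- random_blob(g, 16)
  vv <- voxel_volume_cc(g)
  for (v_pct in c(20, 50, 95)) {
    dd <- dose_at_volume(d, m, volume_pct = v_pct)
    expect_gte(volume_at_dose(d, m, dd), v_pct - 100 * vv / volume_cc(m))
  }
  for (thr in c(4, 10)) {
    v <- volume_at_dose(d, m, thr)
    if (v > 0)
      expect_gte(dose_at_volume(d, m, volume_pct = v), thr - 1e-9)
  }
})

test_that("RTOG conformity index is the isodose-to-target volume ratio", {
  u <- uniform_scene(10)
  # prescription isodose exactly the target
  g <- u$grid
  target <- voxelize_solid(solid_sphere(c(0, 0, 0), 8), g, "T", "PTV_High")
  body <- structure_mask(g, array(TRUE, g$dims), "Body", "Body")
  vals <- array(0, g$dims); vals[target$occupancy] <- 12
  d <- dose_grid(g, vals)
  expect_equal(rtog_ci(d, target, 12, body), 1)
  # independent recomposition
  st <- small_scene()
  p1 <- paint_phase1(st, attr(st, "kept_spheres"))
  ci <- rtog_ci(p1, st$PTV_High, 12, st$Body)
  expect_equal(ci, volume_at_dose(p1, st$Body, 12, "cc") /
                 volume_cc(st$PTV_High))
  expect_error(rtog_ci(d, structure_mask(g, array(FALSE, g$dims)), 12, body),
               "empty")
})

test_that("objective checking gates plans and reports failures readably", {
  u <- uniform_scene(12)
  st <- list(PTV_High = u$mask)
  obj <- tibble::tibble(structure = "PTV_High", metric = "V12Gy",
                        comparator = "ge", lo = 90, hi = NA)
  rep1 <- check_objectives(u$dose, st, obj)
  expect_true(all(rep1$pass))
  expect_true(glance(rep1)$overall_pass)
  hot <- dose_grid(u$grid, array(16, u$grid$dims))
  obj2 <- tibble::tibble(structure = c("PTV_High", "Ring"),
                         metric = c("D0.03cc", "D0.03cc"),
                         comparator = c("le", "le"), lo = c(NA, NA),
                         hi = c(15, 4))
  rep2 <- check_objectives(hot, st, obj2)
  expect_false(rep2$pass[1])
  expect_false(rep2$pass[2])
  expect_match(rep2$note[2], "missing")
  expect_false(glance(rep2)$overall_pass)
})

test_that("plan deltas are zero on self and exact under uniform offsets", {
  st <- small_scene()
  p1 <- paint_phase1(st, attr(st, "kept_spheres"))
  self <- compare_plans(p1, p1, st)
  expect_true(all(self$delta == 0))
  shifted <- dose_grid(p1$grid, p1$dose_gy + 0.1)
  delta <- compare_plans(p1, shifted, st)
  dmean_rows <- delta$metric == "Dmean"
  expect_equal(delta$delta[dmean_rows], rep(0.1, sum(dmean_rows)),
               tolerance = 1e-9)
  # symmetric in its arguments
  expect_equal(compare_plans(shifted, p1, st)$delta, delta$delta)
})
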