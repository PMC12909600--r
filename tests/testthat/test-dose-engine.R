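test_that("an empty sphere set paints a pure base plan", {
  st <- small_scene()
  empty <- attr(st, "kept_spheres")
  empty$centers_mm <- empty$centers_mm[0, ]
  dose <- paint_phase1(st, empty)
  expect_equal(max(dose$dose_gy), 4)
  expect_true(all(dose$dose_gy[st$PTV_Low$occupancy] == 4))
  expect_true(all(dose$dose_gy[!st$PTV_Low$occupancy] <= 4))
})

test_that("the lattice plan meets sphere coverage and the hotspot cap", {
  st <- small_scene()
  kept <- attr(st, "kept_spheres")
  expect_gte(n_spheres(kept), 1L)
  dose <- paint_phase1(st, kept)
  ci <- as.integer((c(0, 0, 0) - dose$grid$origin_mm) /
                     dose$grid$spacing_mm) + 1L
  expect_gte(dose$dose_gy[ci[1], ci[2], ci[3]], 12)
  expect_lte(max(dose$dose_gy), 15)
  expect_true(all(dose$dose_gy >= 0))
  expect_true(all(dose$dose_gy[st$PTV_High$occupancy] >= 12))
  # ring safety by construction
  expect_lte(max(dose$dose_gy[!st$PTV_Low$occupancy]), 4)
  # determinism
  expect_identical(paint_phase1(st, kept)$dose_gy, dose$dose_gy)
})

test_that("multi-sphere painting equals per-sphere superposition by maximum", {
  st <- small_scene(gtv_r = 38, n = 41)
  kept <- attr(st, "kept_spheres")
  expect_gte(n_spheres(kept), 2L)
  batch <- paint_phase1(st, kept)$dose_gy
  acc <- NULL
  for (i in seq_len(n_spheres(kept))) {
    one <- kept
    one$centers_mm <- kept$centers_mm[i, , drop = FALSE]
    d1 <- paint_phase1(st, one)$dose_gy
    acc <- if (is.null(acc)) d1 else pmax(acc, d1)
  }
  expect_equal(batch, acc, tolerance = 1e-12)
})

test_that("painting fails loudly when a sphere cannot reach its dose", {
  st <- small_scene()
  stray <- attr(st, "kept_spheres")
  # a sphere centred outside the GTV only ever sees the 4 Gy bath
  stray$centers_mm <- tibble::tibble(x_mm = 36, y_mm = 0, z_mm = 0)
  expect_error(paint_phase1(st, stray), "constructive failure")
})

test_that("phase 2 paints a uniform fraction with fast penumbra decay", {
  st <- small_scene()
  frac <- paint_phase2(st)
  dm <- mean_dose(frac, st$PTV_Low)
  expect_gte(dm, 3.5)
  expect_lte(dm, 5.5)
  expect_gte(dose_at_volume(frac, st$PTV_Low, volume_pct = 95), 4)
  # beyond 5 sigma the bath is negligible
  far <- !suppressWarnings(expand_mask(st$PTV_Low, 5 * 4))$occupancy
  if (any(far)) expect_lt(max(frac$dose_gy[far]), 0.1)
})

test_that("the painted bath matches its closed-form falloff voxel by voxel", {
  g <- cube_grid(17, 2)
  body <- structure_mask(g, array(TRUE, g$dims), "Body", "Body")
  ptv_low <- voxelize_solid(solid_sphere(c(0, 0, 0), 9), g,
                            "PTV_Low", "PTV_Low")
  st <- list(PTV_Low = ptv_low, GTV = ptv_low, Body = body)
  frac <- paint_phase2(st)
  dist_out <- bf_distance_to_set(g, ptv_low$occupancy)
  oracle <- 4 * exp(-dist_out^2 / (2 * 4^2))
  oracle[!ptv_low$occupancy] <- pmin(oracle[!ptv_low$occupancy], 4)
  oracle[ptv_low$occupancy] <- 4
  expect_equal(frac$dose_gy, array(oracle, g$dims), tolerance = 1e-9)
})

test_that("dose accumulation is additive, order-independent and checked", {
  st <- small_scene()
  p1 <- paint_phase1(st, attr(st, "kept_spheres"))
  f <- paint_phase2(st)
  total <- accumulate_dose(c(list(p1), rep(list(f), 4)))
  expect_identical(total$phase_label, "total")
  # 20 Gy at GTV tissue outside the boosted spheres
  bath <- st$GTV$occupancy & !st$PTV_High$occupancy
  expect_equal(median(total$dose_gy[bath]), 20, tolerance = 0.5)
  # permutation invariance
  total2 <- accumulate_dose(c(rep(list(f), 2), list(p1), rep(list(f), 2)))
  expect_equal(total$dose_gy, total2$dose_gy, tolerance = 1e-12)
  zeros <- dose_grid(p1$grid, array(0, p1$grid$dims))
  expect_equal(max(accumulate_dose(list(zeros, zeros))$dose_gy), 0)
  g2 <- cube_grid(11, 2)
  expect_error(accumulate_dose(list(p1, dose_grid(g2, array(0, g2$dims)))),
               "geometry mismatch")
})
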