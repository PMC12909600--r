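test_that("expansion matches analytic spheres and the exhaustive oracle", {
  g <- cube_grid(55, 1)
  s <- voxelize_solid(solid_sphere(c(0, 0, 0), 20), g)
  e <- expand_mask(s, 5)
  v_true <- 4 / 3 * pi * 2.5^3
  expect_lt(abs(volume_cc(e) - v_true) / v_true, 0.05)
  expect_identical(expand_mask(s, 0)$occupancy, s$occupancy)

  gs <- cube_grid(16, 2)
  blob <- random_blob(gs, 21)
  expect_identical(suppressWarnings(expand_mask(blob, 7))$occupancy,
                   bf_expand(blob, 7)$occupancy)
  expect_warning(expand_mask(blob, 20), "clipped")
})

test_that("retraction matches analytic spheres and the exhaustive oracle", {
  g <- cube_grid(65, 1)
  s <- voxelize_solid(solid_sphere(c(0, 0, 0), 30), g)
  r <- retract_mask(s, 10)
  v_true <- 4 / 3 * pi * 2^3
  expect_lt(abs(volume_cc(r) - v_true) / v_true, 0.05)
  expect_identical(retract_mask(s, 0)$occupancy, s$occupancy)

  tiny <- voxelize_solid(solid_sphere(c(0, 0, 0), 5), cube_grid(21, 1))
  expect_warning(rr <- retract_mask(tiny, 10), "empty")
  expect_true(is_empty_mask(rr))

  gs <- cube_grid(16, 2)
  blob <- random_blob(gs, 22)
  expect_identical(suppressWarnings(retract_mask(blob, 4))$occupancy,
                   bf_retract(blob, 4)$occupancy)
})

test_that("expand and retract satisfy duality, monotonicity and closing", {
  gs <- cube_grid(20, 2)
  for (seed in c(31, 32, 33)) {
    blob <- random_blob(gs, seed)
    m <- 5
    comp <- structure_mask(gs, !blob$occupancy)
    dual <- !suppressWarnings(expand_mask(comp, m))$occupancy
    expect_identical(suppressWarnings(retract_mask(blob, m))$occupancy,
                     array(blob$occupancy & dual, gs$dims))
    v1 <- volume_cc(suppressWarnings(expand_mask(blob, 3)))
    v2 <- volume_cc(suppressWarnings(expand_mask(blob, 6)))
    expect_gte(v2, v1)
    r1 <- volume_cc(suppressWarnings(retract_mask(blob, 3)))
    r2 <- volume_cc(suppressWarnings(retract_mask(blob, 6)))
    expect_lte(r2, r1)
    closed <- suppressWarnings(
      retract_mask(suppressWarnings(expand_mask(blob, m)), m))
    expect_true(all(closed$occupancy[blob$occupancy]))
  }
})

test_that("structure derivation yields nested, disjoint planning volumes", {
  g <- cube_grid(71, 2)
  body <- structure_mask(g, array(TRUE, g$dims), "Body", "Body")
  gtv <- voxelize_solid(solid_sphere(c(0, 0, 0), 30), g, "GTV", "GTV")
  spheres <- generate_lattice(lattice_spec(matrix_extent_mm = 100))
  st <- suppressWarnings(derive_structures(gtv, body, spheres))
  # ring approximates the analytic shell between r = 35 and 65 mm
  v_shell <- 4 / 3 * pi * (6.5^3 - 3.5^3)
  expect_lt(abs(volume_cc(st$Ring) - v_shell) / v_shell, 0.05)
  expect_true(all(st$GTV$occupancy[st$PTV_High$occupancy]))
  expect_true(all(st$PTV_Low$occupancy[st$GTV$occupancy]))
  expect_false(any(st$PTV_High$occupancy & st$Ring$occupancy))
  expect_false(any(st$PTV_Low$occupancy & st$Ring$occupancy))
})

test_that("derivation on a lobed GTV keeps containment and set arithmetic", {
  case <- generate_case(case_spec("thorax", "lobed", c(70, 60, 80), seed = 3))
  spheres <- generate_lattice(
    lattice_spec(center_point_mm = mask_centroid_mm(case$masks$GTV)))
  st <- suppressWarnings(derive_structures(case$masks$GTV, case$masks$Body,
                                           spheres))
  expect_true(all(st$GTV$occupancy[st$PTV_High$occupancy]))
  expect_true(all(st$PTV_Low$occupancy[st$GTV$occupancy]))
  # ring equals brute-force set arithmetic from its definition
  ring_oracle <- suppressWarnings(expand_mask(st$PTV_Low, 30))$occupancy &
    !st$PTV_Low$occupancy & st$Body$occupancy
  expect_identical(st$Ring$occupancy, array(ring_oracle, st$Ring$grid$dims))
  expect_error(derive_structures(st$PTV_Low, st$GTV, spheres),
               "not contained")
})
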