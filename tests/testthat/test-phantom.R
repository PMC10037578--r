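test_that("analytic defect areas match closed forms and numerical oracles", {
  # flat circle: pi r^2
  expect_equal(true_defect_area(phantom_spec("flat", a = 10)), pi * 100)
  # tilting is an isometry: intrinsic area unchanged, projection shrinks
  s60 <- phantom_spec("tilted_plane", a = 10, tilt_deg = 60)
  expect_equal(true_defect_area(s60), pi * 100)
  expect_equal(projected_defect_area(s60), pi * 100 * cos(60 * pi / 180))
  # ellipse
  expect_equal(true_defect_area(phantom_spec("flat", a = 8, b = 5)),
               pi * 40)
  # spherical cap: 2 pi R h, cross-checked against a dense triangulation
  cap <- phantom_spec("spherical_cap", a = 10, cap_radius_R = 20)
  h <- 20 - sqrt(400 - 100)
  expect_equal(true_defect_area(cap), 2 * pi * 20 * h)
  expect_equal(true_defect_area(cap), 336.70, tolerance = 1e-4)
  expect_equal(cap_area_numeric(20, 10), true_defect_area(cap),
               tolerance = 1e-4)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec("flat", a = -1), "positive")
  expect_error(phantom_spec("flat", a = 10, shell_thickness = 0), "positive")
  expect_error(phantom_spec("tilted_plane", a = 10, tilt_deg = 85), "tilt")
  expect_error(phantom_spec("spherical_cap", a = 19, cap_radius_R = 20),
               "too large")
  expect_error(phantom_spec("spherical_cap", a = 5, b = 7,
                            cap_radius_R = 20), "circular")
  expect_error(phantom_spec("flat", a = 10, bone_hu = 100, tissue_hu = 200),
               "threshold")
  expect_error(phantom_spec("flat", a = 10, voxel_spacing = c(0.4, 0, 0.4)),
               "spacing")
  expect_error(phantom_spec("flat", a = 10, volume_extent = c(5, 5, 5)),
               "too small")
})

test_that("noiseless rasterization produces exactly the three materials", {
  ph <- rasterize_phantom(phantom_spec("flat", a = 10))
  vals <- unique(as.vector(ph$volume$values))
  expect_setequal(vals, c(1200, 40, -1000))
})

test_that("rasterization is deterministic under the seed", {
  s <- phantom_spec("flat", a = 10, noise_sd = 25, seed = 99L)
  v1 <- rasterize_phantom(s)$volume$values
  v2 <- rasterize_phantom(s)$volume$values
  expect_identical(v1, v2)
  s2 <- phantom_spec("flat", a = 10, noise_sd = 25, seed = 100L)
  expect_false(identical(v1, rasterize_phantom(s2)$volume$values))
})

test_that("bone voxel volume approximates the analytic shell volume", {
  # plate area x thickness, minus the defect cylinder
  for (s in list(phantom_spec("flat", a = 10, voxel_spacing = c(0.3, 0.3, 0.3)),
                 phantom_spec("tilted_plane", a = 8, tilt_deg = 30,
                              voxel_spacing = c(0.3, 0.3, 0.3)))) {
    ph <- rasterize_phantom(s)
    n_bone <- sum(ph$volume$values == s$bone_hu)
    vox <- prod(s$voxel_spacing)
    plate <- (2 * (s$a + s$floor_margin)) * (2 * (s$b + s$floor_margin))
    shell_vol <- (plate - pi * s$a * s$b) * s$shell_thickness
    # one voxel-layer tolerance on the plate's rim surfaces
    layer <- (plate - pi * s$a * s$b) * max(s$voxel_spacing)
    expect_lt(abs(n_bone * vox - shell_vol), layer)
  }
})

test_that("halving the voxel spacing reduces the shell-volume error", {
  err <- vapply(c(0.6, 0.3), function(h) {
    s <- phantom_spec("flat", a = 10, voxel_spacing = c(h, h, h))
    ph <- rasterize_phantom(s)
    vox <- prod(s$voxel_spacing)
    plate <- (2 * (s$a + s$floor_margin))^2
    shell_vol <- (plate - pi * s$a^2) * s$shell_thickness
    abs(sum(ph$volume$values == s$bone_hu) * vox - shell_vol)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("ground-truth rim lies on the analytic surface and projects smaller", {
  # planar floors: rim points satisfy the plane equation to 1e-9
  s <- phantom_spec("tilted_plane", a = 9, b = 7, tilt_deg = 35)
  gt <- ground_truth(s)
  th <- s$tilt_deg * pi / 180
  n <- c(0, -sin(th), cos(th))
  d <- as.vector(sweep(gt$boundary_polygon, 2, s$floor_center) %*% n)
  expect_lt(max(abs(d)), 1e-9)
  expect_gte(gt$true_area_3d, gt$projected_area)

  # spherical bowl: rim points at distance R from the sphere centre
  sc <- phantom_spec("spherical_cap", a = 10, cap_radius_R = 20)
  gtc <- ground_truth(sc)
  centre <- sc$floor_center + c(0, 0, sc$cap_radius_R)
  r <- sqrt(rowSums(sweep(gtc$boundary_polygon, 2, centre)^2))
  expect_lt(max(abs(r - sc$cap_radius_R)), 1e-9)
  expect_gte(gtc$true_area_3d, gtc$projected_area)
})

test_that("tilting shrinks the projected area by cos(tilt), not the true area", {
  for (tilt in c(10, 30, 55, 75)) {
    s <- phantom_spec("tilted_plane", a = 10, tilt_deg = tilt)
    expect_equal(true_defect_area(s), pi * 100)
    expect_equal(projected_defect_area(s) / true_defect_area(s),
                 cos(tilt * pi / 180))
  }
})

test_that("cohort sampling is seeded, bounded and rejects bad input", {
  expect_error(sample_cohort(0), ">= 1")
  expect_error(sample_cohort(5, list(a_range = c(9, 2))), "range")
  c1 <- sample_cohort(20, seed = 11L)
  c2 <- sample_cohort(20, seed = 11L)
  expect_identical(cohort_manifest(c1), cohort_manifest(c2))
  expect_length(c1, 20)
  man <- cohort_manifest(c1)
  # analytic areas span the configured geometry ranges
  expect_true(all(man$true_area_3d > 0))
  planar <- man$floor_kind != "spherical_cap"
  expect_true(all(man$a[planar] >= 5 & man$a[planar] <= 14))
  expect_true(all(man$tilt_deg <= 45))
})

test_that("phantom specs round-trip through YAML", {
  s <- phantom_spec("spherical_cap", a = 9, cap_radius_R = 22,
                    noise_sd = 25, seed = 7L)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(s, path)
  s2 <- read_phantom_spec(path)
  expect_equal(s2$floor_kind, s$floor_kind)
  expect_equal(s2$a, s$a)
  expect_equal(s2$cap_radius_R, s$cap_radius_R)
  expect_equal(true_defect_area(s2), true_defect_area(s))
})
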