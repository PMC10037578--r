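# shared fixture: one flat noiseless phantom and its surface
flat10 <- local({
  s <- phantom_spec("flat", a = 10)
  ph <- rasterize_phantom(s)
  mask <- largest_component(threshold_bone(ph$volume, 300))
  list(spec = s, ph = ph, mask = mask, mesh = extract_surface(mask))
})

test_that("rim detection recovers the circular defect aperture", {
  rim <- detect_rim(flat10$mesh, flat10$ph$truth)
  expect_gte(nrow(rim$points), 6)
  ctr <- colMeans(rim$points)
  truth_ctr <- flat10$ph$truth$defect_center
  # centroid within one voxel (in-plane)
  expect_lt(sqrt(sum((ctr[1:2] - truth_ctr[1:2])^2)), 0.75)
  # radius within one voxel of 10 mm
  rho <- sqrt((rim$points[, 1] - ctr[1])^2 + (rim$points[, 2] - ctr[2])^2)
  expect_lt(abs(mean(rho) - 10), 0.75)
  # loop is simple in its plane projection
  pc <- prcomp(rim$points)
  expect_true(orbfloor:::.is_simple_polygon(pc$x[, 1:2]))
})

test_that("an intact shell has no detectable rim", {
  arr <- array(FALSE, c(60, 40, 20))
  arr[6:55, 6:35, 9:11] <- TRUE
  mesh <- extract_surface(bone_mask(arr, c(0.5, 0.75, 0.5)))
  expect_error(detect_rim(mesh, c(15, 15, 5)), "no rim|intact")
})

test_that("a plane interpolates exactly at any degree", {
  phi <- seq(0, 2 * pi, length.out = 41)[-41]
  rim <- defect_boundary(cbind(10 * cos(phi), 10 * sin(phi),
                               2 + 0.3 * (10 * cos(phi)) -
                                 0.1 * (10 * sin(phi))))
  for (deg in 1:3) {
    p <- fit_patch(rim, degree = deg)
    expect_lt(p$rms, 1e-9)
  }
})

test_that("a quadratic height field is reproduced coefficient-exactly", {
  # rim on w = u^2 + v^2 over a circle: a planar circle at w = r0^2, so the
  # PCA frame keeps w vertical and the in-plane rotation leaves u^2 + v^2
  # invariant
  r0 <- 8
  phi <- seq(0, 2 * pi, length.out = 61)[-61]
  rim <- defect_boundary(cbind(r0 * cos(phi), r0 * sin(phi), r0^2))
  set.seed(12)
  u <- runif(150, -12, 12); v <- runif(150, -12, 12)
  support <- cbind(u, v, u^2 + v^2)
  p <- fit_patch(rim, support = support, degree = 2)
  expect_lt(p$rms, 1e-9)
  expect_equal(unname(p$coeffs["c20"]), 1, tolerance = 1e-9)
  expect_equal(unname(p$coeffs["c02"]), 1, tolerance = 1e-9)
  expect_equal(unname(p$coeffs["c11"]), 0, tolerance = 1e-9)
})

test_that("a degree-2 patch tracks a sphere closely over the defect footprint", {
  # Extrapolating an annulus fit of a sphere to the defect centre carries
  # the quartic sag term with it: for R = 20, a = 10 and a band of width b
  # the centre offset is roughly (a^2 (a+b)^2 + (2 a b + b^2)^2 / 6) / 8R^3
  # (from the least-squares line through s^2, s = rho^2), so a tight band
  # stays under 0.2 mm while the default 3 mm band allows ~0.4 mm. The
  # surface-area integral is insensitive to that offset; it only feels the
  # gradient, which is why cap areas stay within a couple of percent.
  R <- 20; a <- 10
  phi <- seq(0, 2 * pi, length.out = 73)[-73]
  sphere_w <- function(rho) R - sqrt(R^2 - rho^2)   # sag below the rim plane
  fit_cap <- function(band_width) {
    rim <- defect_boundary(cbind(a * cos(phi), a * sin(phi), sphere_w(a)))
    set.seed(13)
    rho_b <- sqrt(runif(400, a^2, (a + band_width)^2))
    phib <- runif(400, 0, 2 * pi)
    band <- cbind(rho_b * cos(phib), rho_b * sin(phib), sphere_w(rho_b))
    p <- fit_patch(rim, support = band, degree = 2)
    gr <- expand.grid(u = seq(-a, a, by = 0.25), v = seq(-a, a, by = 0.25))
    gr <- gr[gr$u^2 + gr$v^2 <= a^2, ]
    # the PCA frame of a planar circular rim is a rotation about w; rho is
    # preserved, so compare against the sphere in rho
    w_fit <- orbfloor:::.patch_eval(p, gr$u, gr$v) +
      mean(rim$points[, 3]) -
      mean(orbfloor:::.to_frame(rim$points, p$frame)[, 3])
    list(max_dev = max(abs(w_fit - sphere_w(sqrt(gr$u^2 + gr$v^2)))),
         patch = p, rim = rim)
  }
  tight <- fit_cap(0.75)
  expect_lt(tight$max_dev, 0.25)
  wide <- fit_cap(3)
  expect_lt(wide$max_dev, 0.5)
  # the area integral is immune to the centre offset either way
  truth <- 2 * pi * R * (R - sqrt(R^2 - a^2))
  expect_equal(patch_area(wide$patch, wide$rim), truth, tolerance = 0.02)
})

test_that("degenerate rim geometry is rejected with a named deficiency", {
  line <- cbind(seq(0, 10, length.out = 12), 0, 0)
  expect_error(fit_patch(defect_boundary(line), degree = 2),
               "rank-deficient")
  phi <- seq(0, 2 * pi, length.out = 7)[-7]
  tiny <- defect_boundary(cbind(cos(phi), sin(phi), 0))
  expect_error(fit_patch(tiny, degree = 4), "at least")
})

test_that("patch area of a planar disc equals the polygon area", {
  phi <- seq(0, 2 * pi, length.out = 361)[-361]
  rim <- defect_boundary(cbind(10 * cos(phi), 10 * sin(phi), 0))
  p <- fit_patch(rim, degree = 1)
  expect_equal(patch_area(p, rim), pi * 100, tolerance = 0.005)
})

test_that("patch area grows with the surface gradient", {
  phi <- seq(0, 2 * pi, length.out = 181)[-181]
  areas <- vapply(c(0, 0.01, 0.02, 0.04), function(c2) {
    rim_pts <- cbind(8 * cos(phi), 8 * sin(phi), c2 * 64)
    rim <- defect_boundary(rim_pts)
    set.seed(14)
    u <- runif(200, -11, 11); v <- runif(200, -11, 11)
    p <- fit_patch(rim, support = cbind(u, v, c2 * (u^2 + v^2)), degree = 2)
    patch_area(p, rim)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("self-intersecting rim projections are refused", {
  bow <- defect_boundary(rbind(
    c(0, 0, 0), c(4, 4, 0), c(4, 0, 0), c(0, 4, 0),
    c(-2, 2, 0), c(-3, 1, 0)))
  p <- fit_patch(defect_boundary(cbind(10 * cos(seq(0, 6, by = 1)),
                                       10 * sin(seq(0, 6, by = 1)), 0)),
                 degree = 1)
  expect_error(patch_area(p, bow), "self-intersecting")
})

test_that("the full 3D measurement recovers a flat defect within 3%", {
  res <- area_3d(flat10$ph$volume, flat10$ph$truth)
  expect_equal(res$area, true_defect_area(flat10$spec), tolerance = 0.03)
  # audit artifacts are recorded
  expect_s3_class(res$mesh, "triangle_mesh")
  expect_s3_class(res$boundary, "defect_boundary")
  expect_s3_class(res$patch, "polynomial_patch")
  expect_true(sum(res$mask$values) > 0)
})

test_that("the measured area is never below its planar projection", {
  for (kind in list(list("flat", 10, 0, NA), list("tilted_plane", 9, 35, NA),
                    list("spherical_cap", 10, 0, 20))) {
    s <- if (kind[[1]] == "spherical_cap")
      phantom_spec(kind[[1]], a = kind[[2]], cap_radius_R = kind[[4]])
    else phantom_spec(kind[[1]], a = kind[[2]], tilt_deg = kind[[3]])
    ph <- rasterize_phantom(s)
    res <- area_3d(ph$volume, ph$truth)
    # shoelace area of the rim projected into its own fit plane
    loc <- orbfloor:::.to_frame(res$boundary$points, res$patch$frame)
    u <- loc[, 1]; v <- loc[, 2]
    n <- length(u)
    proj <- abs(sum(u * v[c(2:n, 1)] - u[c(2:n, 1)] * v)) / 2
    expect_gte(res$area, proj)
  }
})

test_that("measurement is stable under rigid tilt of the whole floor", {
  sp <- c(0.25, 0.4, 0.25)
  a_flat <- area_3d(rasterize_phantom(
    phantom_spec("flat", a = 10, voxel_spacing = sp))$volume,
    ground_truth(phantom_spec("flat", a = 10, voxel_spacing = sp)))$area
  a_tilt <- area_3d(rasterize_phantom(
    phantom_spec("tilted_plane", a = 10, tilt_deg = 15,
                 voxel_spacing = sp))$volume,
    ground_truth(phantom_spec("tilted_plane", a = 10, tilt_deg = 15,
                              voxel_spacing = sp)))$area
  expect_equal(a_tilt, a_flat, tolerance = 0.005)
})

test_that("STL-exported surfaces can be measured directly", {
  p <- tempfile(fileext = ".stl")
  write_stl(flat10$mesh, p, format = "binary")
  res <- area_3d(read_stl(p), flat10$ph$truth)
  expect_equal(res$area, true_defect_area(flat10$spec), tolerance = 0.03)
})
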