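test_that("a solid cube extracts to a closed surface of the right area", {
  m <- cube_mask(10, spacing = c(1, 1, 1))
  mesh <- extract_surface(m)
  # 10 mm cube: 600 mm^2 up to isosurface discretization (corner chamfers)
  expect_equal(mesh_area(mesh), 600, tolerance = 0.05)
  # watertight: every edge shared by exactly two faces
  edges <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
                 mesh$faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # enclosed volume (divergence theorem) close to 1000 mm^3
  v1 <- mesh$vertices[mesh$faces[, 1], ]
  v2 <- mesh$vertices[mesh$faces[, 2], ]
  v3 <- mesh$vertices[mesh$faces[, 3], ]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
               v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
               v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  expect_equal(abs(vol), 1000, tolerance = 0.05)
})

test_that("surface extraction respects anisotropic spacing and rejects empties", {
  m <- cube_mask(10, spacing = c(0.5, 1, 2))
  mesh <- extract_surface(m)
  # 5 x 10 x 20 mm box: 2*(5*10 + 5*20 + 10*20) = 700 mm^2
  expect_equal(mesh_area(mesh), 700, tolerance = 0.05)
  expect_error(extract_surface(bone_mask(array(FALSE, c(3, 3, 3)),
                                         c(1, 1, 1))), "empty")
})

test_that("mesh_area computes the cross-product face sum", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  expect_identical(mesh_area(tri), 0.5)
  empty <- triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_identical(mesh_area(empty), 0)
})

test_that("icosphere refinement area converges to 4*pi", {
  errs <- vapply(1:3, function(s) {
    ico <- unit_icosphere(s)
    abs(mesh_area(triangle_mesh(ico$vertices, ico$faces)) - 4 * pi)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # error shrinks with refinement
  expect_lt(errs[3] / (4 * pi), 0.01)
})

test_that("mesh_area is invariant under rigid motion", {
  set.seed(8)
  ico <- unit_icosphere(1)
  mesh <- triangle_mesh(ico$vertices * 7, ico$faces)
  a0 <- mesh_area(mesh)
  # random rotation via QR of a Gaussian matrix, plus translation
  qrq <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- triangle_mesh(sweep(mesh$vertices %*% qrq, 2, c(4, -2, 9), "+"),
                         mesh$faces)
  expect_equal(mesh_area(moved), a0, tolerance = 1e-12)
})

test_that("surface area converges to the analytic shell area with spacing", {
  shell_err <- vapply(c(0.6, 0.3), function(h) {
    s <- phantom_spec("flat", a = 8, voxel_spacing = c(h, h, h))
    mesh <- extract_surface(threshold_bone(rasterize_phantom(s)$volume, 300))
    side <- 2 * (s$a + s$floor_margin)
    # both plate faces minus the defect disc, plus outer side walls and the
    # cylindrical defect ring
    expected <- 2 * (side^2 - pi * s$a^2) +
      4 * side * s$shell_thickness + 2 * pi * s$a * s$shell_thickness
    abs(mesh_area(mesh) - expected) / expected
  }, numeric(1))
  expect_lt(shell_err[2], shell_err[1])
  expect_lt(shell_err[2], 0.05)
})

test_that("STL round-trips preserve faces and area in both dialects", {
  ico <- unit_icosphere(2)
  mesh <- triangle_mesh(ico$vertices * 12.5, ico$faces)
  a0 <- mesh_area(mesh)

  bin <- tempfile(fileext = ".stl")
  write_stl(mesh, bin, format = "binary")
  back_b <- read_stl(bin)
  expect_identical(nrow(back_b$faces), nrow(mesh$faces))
  expect_equal(mesh_area(back_b), a0, tolerance = 1e-6)

  # the uint32 triangle-count field matches the face count
  con <- file(bin, "rb"); seek(con, 80)
  nf <- readBin(con, "integer", size = 4, endian = "little"); close(con)
  expect_identical(nf, nrow(mesh$faces))

  asc <- tempfile(fileext = ".stl")
  write_stl(mesh, asc, format = "ascii")
  back_a <- read_stl(asc)
  expect_identical(nrow(back_a$faces), nrow(mesh$faces))
  expect_equal(mesh_area(back_a), mesh_area(back_b), tolerance = 1e-6)

  # single triangle survives exactly
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  p <- tempfile(fileext = ".stl")
  write_stl(tri, p)
  expect_equal(mesh_area(read_stl(p)), 0.5, tolerance = 1e-9)
})

test_that("malformed STL input produces parse errors with a location", {
  p <- tempfile(fileext = ".stl")
  writeLines("not an stl at all", p)
  expect_error(read_stl(p), "malformed")
  # truncated binary: header promises more records than the file holds
  con <- file(p, "wb")
  writeBin(charToRaw(sprintf("%-80s", "x"))[1:80], con)
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(as.raw(rep(0, 60)), con)   # just over one record
  close(con)
  expect_error(read_stl(p), "byte")
})

test_that("meshes written from the bone pipeline survive STL exchange", {
  s <- phantom_spec("flat", a = 6)
  mesh <- extract_surface(threshold_bone(rasterize_phantom(s)$volume, 300))
  p <- tempfile(fileext = ".stl")
  write_stl(mesh, p, format = "binary")
  back <- read_stl(p)
  expect_identical(nrow(back$faces), nrow(mesh$faces))
  expect_equal(mesh_area(back), mesh_area(mesh), tolerance = 1e-6)
})
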