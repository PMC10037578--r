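#' Ordered defect rim loop
#'
#' @param points `n x 3` matrix (n >= 6) of rim points in mm, ordered along
#'   the loop; the loop is closed implicitly (first point is not repeated).
#' @return an object of class `defect_boundary`.
#' @export
defect_boundary <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  if (nrow(points) < 6) stop("a rim loop needs at least 6 points")
  if (any(!is.finite(points))) stop("non-finite rim coordinates")
  structure(list(points = points), class = "defect_boundary")
}

#' @export
print.defect_boundary <- function(x, ...) {
  ctr <- colMeans(x$points)
  cat(sprintf("defect_boundary: %d points, centroid (%.1f, %.1f, %.1f) mm\n",
              nrow(x$points), ctr[1], ctr[2], ctr[3]))
  invisible(x)
}

# area-weighted vertex normals; smooths the per-face jitter of a
# discretized surface
.vertex_normals <- function(mesh) {
  fa <- .face_areas(mesh)
  fn <- .face_normals(mesh) * fa    # weight by face area
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], mesh$faces[, c])
      idx <- as.integer(rownames(acc))
      vn[idx, d] <- vn[idx, d] + acc
    }
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

# TRUE if the closed polygon given by 2-column uv has no self-intersection
.is_simple_polygon <- function(uv) {
  n <- nrow(uv)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  a1 <- uv
  a2 <- uv[nxt, , drop = FALSE]
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) -
      (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
    d2 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) -
      (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
    d3 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) -
      (p2[2] - p1[2]) * (q1[, 1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) -
      (p2[2] - p1[2]) * (q2[, 1] - p1[1])
    d1 * d2 < 0 & d3 * d4 < 0
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip segments adjacent to i
    if (length(js) == 0) next
    if (any(seg_int(a1[i, ], a2[i, ],
                    a1[js, , drop = FALSE], a2[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

#' Detect the defect rim on a bone-surface mesh
#'
#' Automated stand-in for circularly marking the defect on the upright bony
#' floor. Superior-surface vertices (area-weighted vertex normal pointing
#' upward) within a search window around the hint are projected onto their
#' best-fit plane; for each azimuthal bin about the aperture centre, the
#' innermost vertices (the aperture edge cluster) are averaged into one rim
#' point. Two passes re-centre the aperture. Fails when no aperture is
#' present (an intact shell has superior surface arbitrarily close to the
#' centre).
#'
#' @param mesh a [triangle_mesh()] of the bone surface.
#' @param hint approximate defect centre (length-3 mm vector) or a
#'   `ground_truth` object, whose `defect_center` is used.
#' @param search_radius in-plane search radius around the hint, mm.
#' @param up_min minimum upward (z) component of the vertex normal for a
#'   vertex to count as superior surface.
#' @param n_bins number of azimuthal bins forming the loop.
#' @param edge_window thickness of the aperture-edge cluster averaged per
#'   bin, mm.
#' @param min_radius smallest credible aperture radius, mm; a detected rim
#'   below this is treated as "no rim found".
#' @param vn optional precomputed vertex normals (internal reuse).
#' @return a [defect_boundary()].
#' @export
detect_rim <- function(mesh, hint, search_radius = 22, up_min = 0.25,
                       n_bins = 72, edge_window = 0.3, min_radius = 2,
                       vn = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (inherits(hint, "ground_truth")) hint <- hint$defect_center
  hint <- as.numeric(hint)
  stopifnot(length(hint) == 3)

  if (is.null(vn)) vn <- .vertex_normals(mesh)
  v <- mesh$vertices
  sel <- vn[, 3] > up_min &
    (v[, 1] - hint[1])^2 + (v[, 2] - hint[2])^2 <= search_radius^2
  if (sum(sel) < 3 * n_bins / 4)
    stop("no rim found: too few superior-surface vertices near the hint")
  pts <- v[sel, , drop = FALSE]

  # local floor plane from the superior surface around the defect
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  w_axis <- pc$rotation[, 3]
  if (w_axis[3] < 0) w_axis <- -w_axis
  u_axis <- pc$rotation[, 1]
  v_axis <- c(w_axis[2] * u_axis[3] - w_axis[3] * u_axis[2],
              w_axis[3] * u_axis[1] - w_axis[1] * u_axis[3],
              w_axis[1] * u_axis[2] - w_axis[2] * u_axis[1])
  uv <- cbind((pts[, 1] - pc$center[1]) * u_axis[1] +
                (pts[, 2] - pc$center[2]) * u_axis[2] +
                (pts[, 3] - pc$center[3]) * u_axis[3],
              (pts[, 1] - pc$center[1]) * v_axis[1] +
                (pts[, 2] - pc$center[2]) * v_axis[2] +
                (pts[, 3] - pc$center[3]) * v_axis[3])
  h_uv <- c(sum((hint - pc$center) * u_axis), sum((hint - pc$center) * v_axis))

  center <- h_uv
  rim_idx_order <- NULL
  for (pass in 1:2) {
    du <- uv[, 1] - center[1]
    dv <- uv[, 2] - center[2]
    rho <- sqrt(du^2 + dv^2)
    ang <- atan2(dv, du)
    bin <- pmin(floor((ang + pi) / (2 * pi) * n_bins) + 1L, n_bins)
    rim_pts <- matrix(NA_real_, n_bins, 3)
    rim_nrm <- matrix(NA_real_, n_bins, 3)
    rim_ang <- rep(NA_real_, n_bins)
    sel_vn <- vn[sel, , drop = FALSE]
    for (bb in seq_len(n_bins)) {
      in_bin <- which(bin == bb)
      if (length(in_bin) == 0) next
      r0 <- min(rho[in_bin])
      edge <- in_bin[rho[in_bin] <= r0 + edge_window]
      rim_pts[bb, ] <- colMeans(pts[edge, , drop = FALSE])
      nb <- colMeans(sel_vn[edge, , drop = FALSE])
      rim_nrm[bb, ] <- nb / max(sqrt(sum(nb^2)), 1e-300)
      rim_ang[bb] <- stats::median(rho[edge])
    }
    ok <- !is.na(rim_pts[, 1])
    if (sum(ok) < 6) stop("no rim found: aperture edge incomplete")
    if (stats::median(rim_ang[ok]) < min_radius)
      stop("no rim found: shell appears intact near the hint")
    # re-centre on the detected loop
    rim_uv <- cbind(
      (rim_pts[ok, 1] - pc$center[1]) * u_axis[1] +
        (rim_pts[ok, 2] - pc$center[2]) * u_axis[2] +
        (rim_pts[ok, 3] - pc$center[3]) * u_axis[3],
      (rim_pts[ok, 1] - pc$center[1]) * v_axis[1] +
        (rim_pts[ok, 2] - pc$center[2]) * v_axis[2] +
        (rim_pts[ok, 3] - pc$center[3]) * v_axis[3])
    center <- colMeans(rim_uv)
    rim_idx_order <- rim_pts[ok, , drop = FALSE]
    rim_nrm_order <- rim_nrm[ok, , drop = FALSE]
    if (!.is_simple_polygon(rim_uv))
      stop("no rim found: detected loop is self-intersecting")
  }
  out <- defect_boundary(rim_idx_order)
  out$normals <- rim_nrm_order
  out
}

# monomial exponents for a bivariate polynomial of given degree
.poly_exponents <- function(degree) {
  ex <- expand.grid(i = 0:degree, j = 0:degree)
  ex <- ex[ex$i + ex$j <= degree, , drop = FALSE]
  ex[order(ex$i + ex$j, ex$i), ]
}

.poly_design <- function(u, v, expo) {
  m <- matrix(1, length(u), nrow(expo))
  for (k in seq_len(nrow(expo))) m[, k] <- u^expo$i[k] * v^expo$j[k]
  m
}

# world -> patch-frame coordinates
.to_frame <- function(points, frame) {
  sweep(points, 2, frame$origin) %*% t(frame$axes)
}

#' Fit a polynomial height-field patch over the defect rim
#'
#' Constructs an orthonormal local frame from a principal-component analysis
#' of the rim: the w (height) axis is the direction of smallest rim
#' variance, signed superior-facing; u is the leading component and
#' v = w x u. A least-squares polynomial `w = sum c_ij u^i v^j` (total
#' degree `<= degree`) is then fit through the rim plus optional supporting
#' surface points, emulating the surrounding-surface selection a human
#' operator supplies when marking the defect.
#'
#' @param boundary a [defect_boundary()].
#' @param support optional `k x 3` matrix of additional surface points
#'   (e.g. a rim band of mesh vertices) included in the fit.
#' @param degree polynomial total degree (1-4; default 2 captures floor
#'   concavity without rim overfitting). If the design is rank-deficient at
#'   the requested degree — e.g. an exactly planar or conic rim with no
#'   support points — the degree is reduced until the fit is determined, so
#'   a coplanar rim always yields its plane with zero residual; irreducibly
#'   degenerate (collinear) geometry is an error.
#' @return an object of class `polynomial_patch` with the frame,
#'   coefficients and residual RMS.
#' @export
fit_patch <- function(boundary, support = NULL, degree = 2) {
  stopifnot(inherits(boundary, "defect_boundary"))
  if (!degree %in% 1:4) stop("degree must be an integer in 1..4")
  bp <- boundary$points
  pc <- stats::prcomp(bp, center = TRUE, scale. = FALSE)
  w_axis <- pc$rotation[, 3]
  if (abs(w_axis[3]) > 1e-12) {
    if (w_axis[3] < 0) w_axis <- -w_axis
  } else {
    nz <- which(abs(w_axis) > 1e-12)[1]   # degenerate: lexicographic sign
    if (w_axis[nz] < 0) w_axis <- -w_axis
  }
  u_axis <- pc$rotation[, 1]
  v_axis <- c(w_axis[2] * u_axis[3] - w_axis[3] * u_axis[2],
              w_axis[3] * u_axis[1] - w_axis[1] * u_axis[3],
              w_axis[1] * u_axis[2] - w_axis[2] * u_axis[1])
  frame <- list(origin = as.numeric(pc$center),
                axes = rbind(u = u_axis, v = v_axis, w = w_axis))

  pts <- rbind(bp, if (!is.null(support)) as.matrix(support))
  loc <- .to_frame(pts, frame)
  if (nrow(loc) < nrow(.poly_exponents(degree)))
    stop("need at least ", nrow(.poly_exponents(degree)),
         " points to fit degree ", degree)
  # an exactly conic rim with no interior data makes the quadratic design
  # rank-deficient (a conic equation ties the monomials together); reduce
  # the degree until the fit is determined, erroring only when even a
  # plane is degenerate (collinear points)
  deg_fit <- degree
  repeat {
    expo <- .poly_exponents(deg_fit)
    X <- .poly_design(loc[, 1], loc[, 2], expo)
    qrX <- qr(X)
    if (qrX$rank == ncol(X)) break
    if (deg_fit == 1)
      stop("rank-deficient polynomial design: rim/support points are ",
           "degenerate in projection (rank ", qrX$rank, " of ", ncol(X), ")")
    deg_fit <- deg_fit - 1
  }
  coef <- qr.coef(qrX, loc[, 3])
  resid <- loc[, 3] - X %*% coef
  structure(list(frame = frame,
                 coeffs = stats::setNames(as.numeric(coef),
                                          paste0("c", expo$i, expo$j)),
                 exponents = expo,
                 degree = deg_fit,
                 degree_requested = degree,
                 rms = sqrt(mean(resid^2)),
                 n_points = nrow(loc)),
            class = "polynomial_patch")
}

#' @export
print.polynomial_patch <- function(x, ...) {
  cat(sprintf("polynomial_patch: degree %d, %d points, residual RMS %.4g mm\n",
              x$degree, x$n_points, x$rms))
  invisible(x)
}

# evaluate the patch height field at frame coordinates (u, v)
.patch_eval <- function(patch, u, v) {
  drop(.poly_design(u, v, patch$exponents) %*% patch$coeffs)
}

# analytic gradient (dw/du, dw/dv) of the patch height field
.patch_gradient <- function(patch, u, v) {
  ex <- patch$exponents
  wu <- rep(0, length(u))
  wv <- rep(0, length(u))
  for (k in seq_len(nrow(ex))) {
    i <- ex$i[k]; j <- ex$j[k]; ck <- patch$coeffs[k]
    if (i > 0) wu <- wu + ck * i * u^(i - 1) * v^j
    if (j > 0) wv <- wv + ck * j * u^i * v^(j - 1)
  }
  list(wu = wu, wv = wv)
}

# unit normals of the patch surface (superior-facing) at world points,
# evaluated at their (u, v) projection; returns world-frame normals
.patch_normals_at <- function(patch, points) {
  loc <- .to_frame(points, patch$frame)
  g <- .patch_gradient(patch, loc[, 1], loc[, 2])
  nl <- cbind(-g$wu, -g$wv, 1) / sqrt(1 + g$wu^2 + g$wv^2)
  nl %*% patch$frame$axes
}

#' Area of the polynomial patch bounded by the defect rim
#'
#' Integrates the surface measure
#' \deqn{A = \iint_\Omega \sqrt{1 + w_u^2 + w_v^2}\, du\, dv}
#' over the rim's projection \eqn{\Omega} onto the patch frame, by Delaunay
#' triangulation of the projected rim polygon plus an interior Steiner-point
#' grid, lifting every triangle vertex onto the polynomial surface and
#' summing lifted-triangle areas. Converges to the integral as
#' `grid_resolution` shrinks; for a planar patch each lifted triangle lies
#' in the plane, so the result is the projected polygon area exactly.
#'
#' @param patch a `polynomial_patch` from [fit_patch()].
#' @param boundary the [defect_boundary()] delimiting the patch.
#' @param grid_resolution Steiner-point spacing in mm.
#' @return area in mm^2.
#' @export
patch_area <- function(patch, boundary, grid_resolution = 0.25) {
  stopifnot(inherits(patch, "polynomial_patch"),
            inherits(boundary, "defect_boundary"))
  if (grid_resolution <= 0) stop("grid_resolution must be positive")
  loc <- .to_frame(boundary$points, patch$frame)
  poly <- loc[, 1:2, drop = FALSE]
  if (!.is_simple_polygon(poly))
    stop("projected rim polygon is self-intersecting")

  gx <- seq(min(poly[, 1]), max(poly[, 1]), by = grid_resolution)
  gy <- seq(min(poly[, 2]), max(poly[, 2]), by = grid_resolution)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  # a perfectly regular grid is maximally cocircular, which the Delaunay
  # code dislikes; a deterministic sub-micrometre quasirandom offset breaks
  # the degeneracy without affecting the integral
  if (nrow(grid) > 0) {
    i <- seq_len(nrow(grid))
    grid[, 1] <- grid[, 1] + ((i * 0.7548776662) %% 1 - 0.5) * 1e-3 * grid_resolution
    grid[, 2] <- grid[, 2] + ((i * 0.5698402910) %% 1 - 0.5) * 1e-3 * grid_resolution
  }
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), grid)
  grid <- grid[inside, , drop = FALSE]
  # drop Steiner points hugging the rim (degenerate slivers, duplicates)
  if (nrow(grid) > 0) {
    dmin <- .min_dist_to_polyline(grid, poly)
    grid <- grid[dmin > grid_resolution / 2, , drop = FALSE]
  }
  uv <- rbind(poly, grid)
  uv <- uv[!duplicated(paste(round(uv[, 1], 8), round(uv[, 2], 8))), ,
           drop = FALSE]

  # near-degenerate point sets (coincident or cocircular clusters) can make
  # the triangulation bail out; retry once with a deterministic micro-jitter
  dd <- NULL
  for (eps in grid_resolution * c(0, 1e-3, 1e-2)) {
    i <- seq_len(nrow(uv))
    j1 <- ((i * 0.8191725134) %% 1 - 0.5) * eps
    j2 <- ((i * 0.6180339887) %% 1 - 0.5) * eps
    try_uv <- cbind(uv[, 1] + j1, uv[, 2] + j2)
    # deldir prints diagnostics on its error path; keep the log clean
    utils::capture.output(
      dd <- tryCatch(deldir::deldir(try_uv[, 1], try_uv[, 2],
                                    suppressMsge = TRUE),
                     error = function(e) NULL),
      file = nullfile())
    if (!is.null(dd)) {
      uv <- try_uv
      break
    }
  }
  if (is.null(dd)) stop("Delaunay triangulation of the rim interior failed")
  tris <- .triangles_from_edges(dd$delsgs$ind1, dd$delsgs$ind2)
  xs <- matrix(uv[tris, 1], nrow = 3, byrow = TRUE)
  ys <- matrix(uv[tris, 2], nrow = 3, byrow = TRUE)
  # keep triangles whose centroid lies inside the rim polygon
  cent <- cbind(colMeans(xs), colMeans(ys))
  keep <- mgcv::in.out(rbind(poly, poly[1, ]), cent)
  if (!any(keep)) stop("triangulation produced no interior triangles")
  xs <- xs[, keep, drop = FALSE]
  ys <- ys[, keep, drop = FALSE]
  ws <- matrix(.patch_eval(patch, as.vector(xs), as.vector(ys)), nrow = 3)
  e1x <- xs[2, ] - xs[1, ]; e1y <- ys[2, ] - ys[1, ]; e1w <- ws[2, ] - ws[1, ]
  e2x <- xs[3, ] - xs[1, ]; e2y <- ys[3, ] - ys[1, ]; e2w <- ws[3, ] - ws[1, ]
  cx <- e1y * e2w - e1w * e2y
  cy <- e1w * e2x - e1x * e2w
  cz <- e1x * e2y - e1y * e2x
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

# triangles of a Delaunay triangulation from its edge list: a triple
# a < b < c is a triangle iff all three edges are present; each is found
# once through its lowest edge (a, b)
.triangles_from_edges <- function(i1, i2) {
  a <- pmin(i1, i2)
  b <- pmax(i1, i2)
  n <- max(b)
  adj <- split(b, factor(a, levels = seq_len(n)))   # neighbours above own index
  out <- vector("list", length(a))
  for (e in seq_along(a)) {
    na <- adj[[a[e]]]
    nb <- adj[[b[e]]]
    common <- na[na %in% nb]                        # all common c satisfy c > b
    if (length(common))
      out[[e]] <- cbind(a[e], b[e], common, deparse.level = 0)
  }
  do.call(rbind, out)
}

# minimum distance from each point to a closed polyline
.min_dist_to_polyline <- function(points, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  dmin <- rep(Inf, nrow(points))
  for (s in seq_len(n)) {
    a <- poly[s, ]
    b <- poly[nxt[s], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t0 <- if (len2 == 0) rep(0, nrow(points)) else
      pmin(1, pmax(0, ((points[, 1] - a[1]) * ab[1] +
                         (points[, 2] - a[2]) * ab[2]) / len2))
    dx <- points[, 1] - (a[1] + t0 * ab[1])
    dy <- points[, 2] - (a[2] + t0 * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Default configuration for the surface-based 3D measurement
#'
#' @param hu_min bone threshold, HU.
#' @param connectivity component connectivity (6 or 26).
#' @param degree polynomial patch degree.
#' @param band rim support band width, mm: superior-surface mesh vertices
#'   within this distance outside the rim join the patch fit.
#' @param grid_resolution Steiner-point spacing for area integration, mm.
#' @param search_radius,up_min,n_bins,edge_window,min_radius rim-detection
#'   parameters, see [detect_rim()].
#' @param mid_surface report the defect on the shell mid-surface: rim and
#'   support points, detected on the superior face, are offset inward by
#'   half the locally estimated shell thickness. A curved defect measured
#'   on the superior face alone is smaller than the mid-surface defect by
#'   roughly a factor `(1 - t/2R)^2`; the offset removes that bias and is a
#'   rigid translation (no effect) for planar floors.
#' @return a named list.
#' @export
measure3d_config <- function(hu_min = 300, connectivity = 26, degree = 2,
                             band = 3, grid_resolution = 0.25,
                             search_radius = 22, up_min = 0.25, n_bins = 72,
                             edge_window = 0.3, min_radius = 2,
                             mid_surface = TRUE) {
  list(hu_min = hu_min, connectivity = connectivity, degree = degree,
       band = band, grid_resolution = grid_resolution,
       search_radius = search_radius, up_min = up_min, n_bins = n_bins,
       edge_window = edge_window, min_radius = min_radius,
       mid_surface = mid_surface)
}

#' Surface-based 3D defect area, end to end
#'
#' Composition of the full surface pipeline: HU thresholding, virtual
#' tissue dissection (largest component), isosurface extraction, rim
#' detection, polynomial patch fit over rim plus support band, and patch
#' area integration. Accepts either a HU volume or an already-extracted
#' surface mesh (e.g. read from STL).
#'
#' @param x a [voxel_volume()] or [triangle_mesh()].
#' @param hint approximate defect centre (mm) or `ground_truth`.
#' @param config a [measure3d_config()].
#' @return a list of class `area3d_result`: `area` (mm^2) plus the
#'   intermediate artifacts `mask`, `mesh`, `boundary`, `patch` for audit.
#' @export
area_3d <- function(x, hint, config = measure3d_config()) {
  mask <- NULL
  if (inherits(x, "voxel_volume")) {
    mask <- largest_component(threshold_bone(x, config$hu_min),
                              config$connectivity)
    mesh <- extract_surface(mask)
  } else if (inherits(x, "triangle_mesh")) {
    mesh <- x
  } else stop("x must be a voxel_volume or triangle_mesh")

  vn <- .vertex_normals(mesh)
  boundary <- detect_rim(mesh, hint,
                         search_radius = config$search_radius,
                         up_min = config$up_min, n_bins = config$n_bins,
                         edge_window = config$edge_window,
                         min_radius = config$min_radius, vn = vn)
  support_idx <- .rim_support_band(mesh, boundary, band = config$band,
                                   up_min = config$up_min, vn = vn)
  support <- mesh$vertices[support_idx, , drop = FALSE]

  # report the defect on the shell mid-surface: rim and support sit on the
  # superior face, half a shell thickness away; offset them inward along
  # the normals of a preliminary patch fit so a curved defect is not shrunk
  # by the face-vs-mid-surface radius difference. For a planar floor the
  # offset is a rigid translation and changes nothing.
  t_shell <- NA_real_
  if (isTRUE(config$mid_surface)) {
    t_shell <- .estimate_shell_thickness(mesh, vn, support_idx,
                                         up_min = config$up_min)
    if (is.finite(t_shell)) {
      patch0 <- fit_patch(boundary, support = support,
                          degree = config$degree)
      boundary$points <- boundary$points -
        .patch_normals_at(patch0, boundary$points) * (t_shell / 2)
      support <- support - .patch_normals_at(patch0, support) * (t_shell / 2)
    }
  }

  patch <- fit_patch(boundary, support = support, degree = config$degree)
  area <- patch_area(patch, boundary,
                     grid_resolution = config$grid_resolution)
  structure(list(area = area, mask = mask, mesh = mesh,
                 boundary = boundary, patch = patch,
                 n_support = nrow(support), shell_thickness = t_shell),
            class = "area3d_result")
}

#' @export
print.area3d_result <- function(x, ...) {
  cat(sprintf("area_3d: %.2f mm^2 (rim of %d points, patch RMS %.3g mm)\n",
              x$area, nrow(x$boundary$points), x$patch$rms))
  invisible(x)
}

# superior-surface mesh vertices within `band` mm outside the rim polygon,
# used to stabilise the patch fit
.rim_support_band <- function(mesh, boundary, band = 3, up_min = 0.25,
                              vn = NULL) {
  bp <- boundary$points
  pc <- stats::prcomp(bp, center = TRUE, scale. = FALSE)
  axes <- pc$rotation
  if (axes[3, 3] < 0) axes[, 3] <- -axes[, 3]
  loc_b <- sweep(bp, 2, pc$center) %*% axes
  if (is.null(vn)) vn <- .vertex_normals(mesh)
  v <- mesh$vertices
  near <- vn[, 3] > up_min
  loc_v <- sweep(v[near, , drop = FALSE], 2, pc$center) %*% axes
  # outside the polygon, within band of it, and close to the rim plane
  poly <- loc_b[, 1:2, drop = FALSE]
  outside <- !mgcv::in.out(rbind(poly, poly[1, ]), loc_v[, 1:2, drop = FALSE])
  w_ok <- abs(loc_v[, 3]) < 2 * band + diff(range(loc_b[, 3]))
  cand <- which(outside & w_ok)
  if (length(cand) == 0) return(integer(0))
  dmin <- .min_dist_to_polyline(loc_v[cand, 1:2, drop = FALSE], poly)
  which(near)[cand[dmin <= band]]
}

# median perpendicular shell thickness: distance from a sample of superior
# band vertices to the nearest inferior-surface vertex
.estimate_shell_thickness <- function(mesh, vn, support_idx,
                                      up_min = 0.25, max_search = 6,
                                      n_sample = 200) {
  v <- mesh$vertices
  if (length(support_idx) == 0) return(NA_real_)
  sup <- v[support_idx, , drop = FALSE]
  lo <- apply(sup, 2, min) - max_search
  hi <- apply(sup, 2, max) + max_search
  inf_idx <- which(vn[, 3] < -up_min &
                     v[, 1] >= lo[1] & v[, 1] <= hi[1] &
                     v[, 2] >= lo[2] & v[, 2] <= hi[2] &
                     v[, 3] >= lo[3] & v[, 3] <= hi[3])
  if (length(inf_idx) == 0) return(NA_real_)
  inf <- v[inf_idx, , drop = FALSE]
  if (nrow(sup) > n_sample)
    sup <- sup[round(seq(1, nrow(sup), length.out = n_sample)), , drop = FALSE]
  d <- vapply(seq_len(nrow(sup)), function(i) {
    min(sqrt((inf[, 1] - sup[i, 1])^2 + (inf[, 2] - sup[i, 2])^2 +
               (inf[, 3] - sup[i, 3])^2))
  }, numeric(1))
  stats::median(d[d <= max_search])
}
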