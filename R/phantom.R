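#' Phantom specification for a synthetic orbital-floor CT volume
#'
#' Describes a thin bone shell (the orbital-floor analog) pierced by a defect
#' of analytically known area, embedded in soft tissue above and air (the
#' maxillary sinus) below. The shell is either a plane (optionally tilted
#' about the mediolateral x axis) or a spherical bowl of radius
#' `cap_radius_R`; the defect is an ellipse (semi-axes `a`, `b`) in the
#' floor's intrinsic plane, or a circle on the spherical bowl.
#'
#' Coordinates: x mediolateral, y anteroposterior, z superoinferior, all mm.
#' Coronal slices are constant-y planes. Voxel `(i,j,k)` (1-based) has its
#' centre at `((i-1)*dx, (j-1)*dy, (k-1)*dz)`; there is no origin offset.
#'
#' @param floor_kind one of `"flat"`, `"tilted_plane"`, `"spherical_cap"`.
#' @param a,b defect semi-axes in mm, measured in the floor's intrinsic
#'   plane. For `spherical_cap` the defect must be circular (`a == b`),
#'   giving a cap of base radius `a`.
#' @param tilt_deg rotation of the floor about the mediolateral axis,
#'   degrees in `[0, 80]`. Ignored unless `floor_kind == "tilted_plane"`.
#' @param cap_radius_R sphere radius in mm for `spherical_cap`.
#' @param shell_thickness bone shell thickness in mm (perpendicular).
#' @param bone_hu,tissue_hu,air_hu Hounsfield values of the three materials.
#' @param noise_sd additive Gaussian noise SD in HU (0 disables noise).
#' @param voxel_spacing `(dx, dy, dz)` in mm; the default 0.75 mm along y
#'   matches a 0.75 mm coronal reformation slice thickness.
#' @param volume_extent box size `(ex, ey, ez)` in mm, or `NULL` to size the
#'   box automatically around the floor plate with a 3 mm margin.
#' @param floor_margin plate margin beyond the defect rim, mm. The floor is
#'   a finite plate extending this far beyond the defect in intrinsic
#'   coordinates (clamped to `0.95 * cap_radius_R` for spherical bowls).
#' @param seed integer seed used for the noise field.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(floor_kind = c("flat", "tilted_plane", "spherical_cap"),
                         a = 10, b = a,
                         tilt_deg = 0,
                         cap_radius_R = 20,
                         shell_thickness = 1.2,
                         bone_hu = 1200, tissue_hu = 40, air_hu = -1000,
                         noise_sd = 0,
                         voxel_spacing = c(0.4, 0.75, 0.4),
                         volume_extent = NULL,
                         floor_margin = 8,
                         seed = 1L) {
  floor_kind <- match.arg(floor_kind)
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (a <= 0 || b <= 0) stop("defect semi-axes must be positive")
  if (shell_thickness <= 0) stop("shell_thickness must be positive")
  if (tilt_deg < 0 || tilt_deg > 80) stop("tilt_deg must lie in [0, 80]")
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0))
    stop("voxel_spacing must be three positive values")
  if (!(bone_hu > tissue_hu && tissue_hu > air_hu))
    stop("need bone_hu > tissue_hu > air_hu for a usable bone threshold")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (floor_margin < 3) stop("floor_margin must be at least 3 mm (rim support band)")
  if (floor_kind == "spherical_cap") {
    if (cap_radius_R <= 0) stop("cap_radius_R must be positive")
    if (abs(a - b) > 1e-12)
      stop("spherical_cap defects must be circular (a == b)")
    if (a > 0.9 * cap_radius_R)
      stop("cap defect too large: need a <= 0.9 * cap_radius_R")
  }
  if (floor_kind != "tilted_plane") tilt_deg <- if (floor_kind == "flat") 0 else tilt_deg

  spec <- structure(list(
    floor_kind = floor_kind, a = a, b = b, tilt_deg = tilt_deg,
    cap_radius_R = cap_radius_R, shell_thickness = shell_thickness,
    bone_hu = bone_hu, tissue_hu = tissue_hu, air_hu = air_hu,
    noise_sd = noise_sd, voxel_spacing = as.numeric(voxel_spacing),
    volume_extent = volume_extent, floor_margin = floor_margin,
    seed = as.integer(seed)
  ), class = "phantom_spec")

  spec$volume_extent <- .phantom_extent(spec)
  spec$floor_center <- .phantom_center(spec)
  .validate_extent(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", x$floor_kind,
      sprintf("a=%.2f b=%.2f mm", x$a, x$b))
  if (x$floor_kind == "tilted_plane") cat(sprintf(" tilt=%.1f deg", x$tilt_deg))
  if (x$floor_kind == "spherical_cap") cat(sprintf(" R=%.1f mm", x$cap_radius_R))
  cat(sprintf("\n  extent %s mm, spacing %s mm, noise_sd %.1f HU, seed %d\n",
              paste(round(x$volume_extent, 1), collapse = "x"),
              paste(x$voxel_spacing, collapse = "/"), x$noise_sd, x$seed))
  invisible(x)
}

# plate half-extent in intrinsic coordinates
.plate_halfwidths <- function(spec) {
  m <- spec$floor_margin
  if (spec$floor_kind == "spherical_cap") {
    rho_max <- min(spec$a + m, 0.95 * spec$cap_radius_R)
    c(rho_max, rho_max)
  } else {
    c(spec$a + m, spec$b + m)
  }
}

.phantom_extent <- function(spec) {
  if (!is.null(spec$volume_extent)) {
    ex <- as.numeric(spec$volume_extent)
    if (length(ex) != 3 || any(ex <= 0)) stop("volume_extent must be three positive values")
    return(ex)
  }
  hw <- .plate_halfwidths(spec)
  t2 <- spec$shell_thickness / 2
  margin <- 3
  if (spec$floor_kind == "spherical_cap") {
    R <- spec$cap_radius_R
    rim_h <- R - sqrt(R^2 - hw[1]^2)
    c(2 * (hw[1] + margin),
      2 * (hw[1] + margin),
      rim_h + spec$shell_thickness + 2 * margin)
  } else {
    th <- spec$tilt_deg * pi / 180
    hz <- hw[2] * sin(th) + t2 * cos(th) + margin
    c(2 * (hw[1] + margin),
      2 * (hw[2] * cos(th) + t2 * sin(th) + margin),
      2 * max(hz, t2 + margin))
  }
}

.phantom_center <- function(spec) {
  ex <- spec$volume_extent
  if (spec$floor_kind == "spherical_cap") {
    # apex of the bowl sits low so the rim fits above it
    c(ex[1] / 2, ex[2] / 2, spec$shell_thickness / 2 + 3)
  } else {
    ex / 2
  }
}

.validate_extent <- function(spec) {
  s2 <- spec
  s2$volume_extent <- NULL
  auto <- .phantom_extent(s2)
  if (any(spec$volume_extent < auto - 1e-9))
    stop("volume_extent too small to contain the floor plate (need >= ",
         paste(round(auto, 1), collapse = " x "), " mm)")
  invisible(TRUE)
}

#' Analytic area of the removed defect surface
#'
#' Closed form for the intrinsic (3D) area of the surface patch removed from
#' the floor: an ellipse `pi*a*b` for planar floors (tilting is an isometry
#' and leaves the intrinsic area unchanged), and the spherical-cap area
#' `2*pi*R*h` with `h = R - sqrt(R^2 - a^2)` for spherical bowls.
#'
#' @param spec a [phantom_spec()].
#' @return defect area in mm^2.
#' @export
true_defect_area <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$floor_kind == "spherical_cap") {
    R <- spec$cap_radius_R
    h <- R - sqrt(R^2 - spec$a^2)
    2 * pi * R * h
  } else {
    pi * spec$a * spec$b
  }
}

#' Analytic area of the defect rim projected onto the axial plane
#'
#' @param spec a [phantom_spec()].
#' @return projected (axial-footprint) area in mm^2; always `<=`
#'   [true_defect_area()].
#' @export
projected_defect_area <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$floor_kind == "spherical_cap") {
    pi * spec$a^2
  } else {
    pi * spec$a * spec$b * cos(spec$tilt_deg * pi / 180)
  }
}

#' Analytic defect rim polygon
#'
#' @param spec a [phantom_spec()].
#' @param n_points number of vertices on the rim loop.
#' @return a `ground_truth` object: list with `true_area_3d`,
#'   `boundary_polygon` (closed loop stored open, `n_points x 3`, mm) and
#'   `projected_area`.
#' @export
ground_truth <- function(spec, n_points = 360) {
  stopifnot(inherits(spec, "phantom_spec"), n_points >= 6)
  ctr <- spec$floor_center
  phi <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  if (spec$floor_kind == "spherical_cap") {
    R <- spec$cap_radius_R
    h <- R - sqrt(R^2 - spec$a^2)
    poly <- cbind(ctr[1] + spec$a * cos(phi),
                  ctr[2] + spec$a * sin(phi),
                  ctr[3] + h)
  } else {
    th <- spec$tilt_deg * pi / 180
    u_hat <- c(1, 0, 0)
    v_hat <- c(0, cos(th), sin(th))
    poly <- outer(spec$a * cos(phi), u_hat) + outer(spec$b * sin(phi), v_hat)
    poly <- sweep(poly, 2, ctr, "+")
  }
  structure(list(true_area_3d = true_defect_area(spec),
                 boundary_polygon = poly,
                 projected_area = projected_defect_area(spec),
                 defect_center = colMeans(poly)),
            class = "ground_truth")
}

# run code with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Rasterize a phantom specification into a CT-like HU volume
#'
#' Voxels whose centre lies within `shell_thickness/2` perpendicular
#' distance of the floor surface, inside the floor plate and outside the
#' defect, receive `bone_hu`. Remaining voxels receive `tissue_hu` above the
#' floor (orbit side) and `air_hu` below it (maxillary sinus side). With
#' `noise_sd > 0`, seeded Gaussian noise is added to every voxel.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `volume` (a [voxel_volume()]) and `truth`
#'   (a `ground_truth`, in the same mm frame as the volume).
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing
  ex <- spec$volume_extent
  dims <- pmax(ceiling(ex / sp) + 1L, 2L)
  xs <- (seq_len(dims[1]) - 1) * sp[1]
  ys <- (seq_len(dims[2]) - 1) * sp[2]
  zs <- (seq_len(dims[3]) - 1) * sp[3]
  ctr <- spec$floor_center
  t2 <- spec$shell_thickness / 2
  hw <- .plate_halfwidths(spec)

  if (spec$floor_kind == "spherical_cap") {
    R <- spec$cap_radius_R
    sz <- ctr[3] + R                      # sphere centre (above the bowl apex)
    rho2_xy <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+")    # nx x ny
    r3 <- sqrt(outer(as.vector(rho2_xy), (zs - sz)^2, "+"))    # (nx*ny) x nz
    d_perp <- r3 - R                     # signed: + outside sphere (below bowl)
    lower <- rep(zs <= sz, each = dims[1] * dims[2])
    rho_surf <- R * sqrt(as.vector(rho2_xy)) / pmax(r3, 1e-12)
    shell <- abs(d_perp) <= t2 & lower & rho_surf <= hw[1] & rho_surf >= spec$a
    vals <- ifelse(d_perp > 0 & lower, spec$air_hu, spec$tissue_hu)
    vals[shell] <- spec$bone_hu
  } else {
    th <- spec$tilt_deg * pi / 180
    # separable geometry: u depends on x only, (v, d_perp) on (y, z) only
    u <- xs - ctr[1]
    v_jk <- outer((ys - ctr[2]) * cos(th), (zs - ctr[3]) * sin(th), "+")   # ny x nz
    d_jk <- outer((ys - ctr[2]) * -sin(th), (zs - ctr[3]) * cos(th), "+")  # ny x nz
    in_u <- abs(u) <= hw[1]
    in_slab <- abs(d_jk) <= t2 & abs(v_jk) <= hw[2]
    defect_uv <- outer((u / spec$a)^2, as.vector((v_jk / spec$b)^2), "+") <= 1
    shell <- outer(in_u, as.vector(in_slab), "&") & !defect_uv
    base_jk <- ifelse(d_jk >= 0, spec$tissue_hu, spec$air_hu)
    vals <- rep(as.vector(base_jk), each = dims[1])
    vals[shell] <- spec$bone_hu
  }

  vol <- array(vals, dim = dims)
  if (spec$noise_sd > 0) {
    vol <- vol + .with_seed(spec$seed,
                            array(stats::rnorm(length(vol), 0, spec$noise_sd),
                                  dim = dims))
  }
  list(volume = voxel_volume(vol, sp), truth = ground_truth(spec))
}

#' Sample a cohort of phantom specifications
#'
#' Draws `n` phantom geometries spanning flat, tilted and spherical-bowl
#' floors with defect sizes whose analytic areas cover roughly the range
#' reported for surgical orbital-floor fracture cohorts (tens to ~650 mm^2).
#' Deterministic under `seed`.
#'
#' @param n cohort size (`>= 1`).
#' @param param_ranges named list overriding any of: `kind_probs` (named
#'   probabilities for the three floor kinds), `a_range`, `b_range` (mm,
#'   planar defect semi-axes), `cap_a_range` (mm, cap base radius),
#'   `tilt_range` (degrees), `R_range` (mm, bowl radius), `noise_sd` (HU),
#'   `shell_thickness` (mm).
#' @param seed integer seed.
#' @return list of [phantom_spec()] objects with per-case seeds.
#' @export
sample_cohort <- function(n, param_ranges = list(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  pr <- utils::modifyList(list(
    kind_probs = c(flat = 0.15, tilted_plane = 0.45, spherical_cap = 0.40),
    a_range = c(5, 14), b_range = c(5, 14),
    cap_a_range = c(5, 12),
    tilt_range = c(5, 45),
    R_range = c(15, 30),
    noise_sd = 25,
    shell_thickness = 1.2
  ), param_ranges)
  for (nm in c("a_range", "b_range", "cap_a_range", "tilt_range", "R_range")) {
    if (length(pr[[nm]]) != 2 || diff(pr[[nm]]) < 0)
      stop("empty or malformed range: ", nm)
  }
  if (!all(names(pr$kind_probs) %in%
           c("flat", "tilted_plane", "spherical_cap")) || sum(pr$kind_probs) <= 0)
    stop("malformed kind_probs")

  .with_seed(seed, {
    kinds <- sample(names(pr$kind_probs), n, replace = TRUE,
                    prob = pr$kind_probs)
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      if (kinds[i] == "spherical_cap") {
        R <- stats::runif(1, pr$R_range[1], pr$R_range[2])
        hi <- min(pr$cap_a_range[2], 0.9 * R)
        a <- stats::runif(1, min(pr$cap_a_range[1], hi), hi)
        phantom_spec("spherical_cap", a = a, b = a, cap_radius_R = R,
                     shell_thickness = pr$shell_thickness,
                     noise_sd = pr$noise_sd, seed = case_seeds[i])
      } else {
        tilt <- if (kinds[i] == "tilted_plane")
          stats::runif(1, pr$tilt_range[1], pr$tilt_range[2]) else 0
        phantom_spec(kinds[i],
                     a = stats::runif(1, pr$a_range[1], pr$a_range[2]),
                     b = stats::runif(1, pr$b_range[1], pr$b_range[2]),
                     tilt_deg = tilt,
                     shell_thickness = pr$shell_thickness,
                     noise_sd = pr$noise_sd, seed = case_seeds[i])
      }
    })
  })
}

#' Cohort manifest as a data frame
#'
#' One row per case: identifier, geometry parameters and the analytic
#' ground-truth areas.
#'
#' @param specs list of [phantom_spec()] (e.g. from [sample_cohort()]).
#' @return a data.frame.
#' @export
cohort_manifest <- function(specs) {
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE, "phantom_spec")))
  do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(case_id = sprintf("case_%03d", i),
               floor_kind = s$floor_kind, a = s$a, b = s$b,
               tilt_deg = s$tilt_deg,
               cap_radius_R = ifelse(s$floor_kind == "spherical_cap",
                                     s$cap_radius_R, NA_real_),
               shell_thickness = s$shell_thickness,
               noise_sd = s$noise_sd, seed = s$seed,
               true_area_3d = true_defect_area(s),
               projected_area = projected_defect_area(s))
  }))
}
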