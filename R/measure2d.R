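#' Per-slice mediolateral defect widths
#'
#' Container for the slice-based 2D protocol: one mediolateral width per
#' coronal slice in which the defect is evident, plus the slice thickness.
#'
#' @param widths positive widths in mm, ordered anteroposteriorly.
#' @param slice_thickness slice thickness d in mm.
#' @param y optional slice positions (mm), for bookkeeping.
#' @return an object of class `slice_width_series`.
#' @export
slice_width_series <- function(widths, slice_thickness, y = NULL) {
  widths <- as.numeric(widths)
  if (length(widths) < 1) stop("need at least one slice width")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("all widths must be positive and finite")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be positive")
  if (!is.null(y) && length(y) != length(widths))
    stop("y must match widths in length")
  structure(list(widths = widths, slice_thickness = slice_thickness, y = y),
            class = "slice_width_series")
}

#' @export
print.slice_width_series <- function(x, ...) {
  cat(sprintf("slice_width_series: %d slices, d = %.3g mm, widths %.2f-%.2f mm\n",
              length(x$widths), x$slice_thickness,
              min(x$widths), max(x$widths)))
  invisible(x)
}

#' Measure per-slice mediolateral defect widths
#'
#' Emulates the manual ruler protocol: in every coronal (constant-y) slice
#' where the defect is evident, the width is the single straight
#' mediolateral extent of the defect — not the sum of disjoint segments, so
#' multi-fragment slices over-count gaps by design, as the manual ruler
#' does.
#'
#' Two inputs are supported: the analytic rim polygon of a phantom
#' (`ground_truth`), intersected exactly with each slice plane, and a
#' segmented [bone_mask()], where the defect in each slice is the run of
#' bone-free columns interrupting the floor.
#'
#' @param x a `ground_truth` or [bone_mask()].
#' @param ... passed to methods.
#' @return a [slice_width_series()].
#' @export
slice_widths <- function(x, ...) UseMethod("slice_widths")

#' @rdname slice_widths
#' @param slice_thickness coronal slice thickness d in mm (default 0.75).
#' @param offset y position of the k = 0 slice plane, mm.
#' @param jitter_sd optional inter-rater jitter: per-slice Gaussian
#'   perturbation of the measured width, SD in mm (seeded).
#' @param seed seed for the jitter.
#' @export
slice_widths.ground_truth <- function(x, slice_thickness = 0.75, offset = 0,
                                      jitter_sd = 0, seed = 1L, ...) {
  poly <- x$boundary_polygon
  yr <- range(poly[, 2])
  ks <- seq(ceiling((yr[1] - offset) / slice_thickness),
            floor((yr[2] - offset) / slice_thickness))
  if (length(ks) == 0) stop("no coronal slice plane intersects the defect")
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  widths <- numeric(0)
  ys <- numeric(0)
  for (k in ks) {
    yk <- offset + k * slice_thickness
    y1 <- poly[, 2]
    y2 <- poly[nxt, 2]
    cross <- (y1 - yk) * (y2 - yk) <= 0 & y1 != y2
    if (!any(cross)) next
    tt <- (yk - y1[cross]) / (y2[cross] - y1[cross])
    xs <- poly[cross, 1] + tt * (poly[nxt, 1][cross] - poly[cross, 1])
    w <- max(xs) - min(xs)
    if (w > 0) {
      widths <- c(widths, w)
      ys <- c(ys, yk)
    }
  }
  if (length(widths) == 0) stop("no coronal slice plane intersects the defect")
  if (jitter_sd > 0) {
    widths <- .with_seed(seed,
                         pmax(widths + stats::rnorm(length(widths), 0, jitter_sd),
                              1e-6))
  }
  slice_width_series(widths, slice_thickness, y = ys)
}

#' @rdname slice_widths
#' @param hint approximate defect centre, mm (length-3; only x and y used).
#' @param search_radius half-width of the in-plane search window, mm.
#' @export
slice_widths.bone_mask <- function(x, hint, search_radius = 25,
                                   jitter_sd = 0, seed = 1L, ...) {
  sp <- x$spacing
  d <- dim(x$values)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  ix <- which(abs(xs - hint[1]) <= search_radius)
  iy <- which(abs(ys - hint[2]) <= search_radius)
  if (length(ix) == 0 || length(iy) == 0)
    stop("search window contains no voxels")
  hx <- which.min(abs(xs - hint[1]))
  widths <- numeric(0)
  ypos <- numeric(0)
  for (j in iy) {
    # columns of this coronal slice containing any bone
    has_bone <- apply(x$values[ix, j, , drop = FALSE], 1, any)
    bx <- which(has_bone)
    if (length(bx) < 2) next
    gap <- setdiff(seq(min(bx), max(bx)), bx)
    if (length(gap) == 0) next
    runs <- split(gap, cumsum(c(1, diff(gap) != 1)))
    # the run containing the hint column, else the widest one
    hit <- which(vapply(runs, function(r) {
      hx >= ix[1] + r[1] - 1 && hx <= ix[1] + r[length(r)] - 1
    }, TRUE))
    run <- if (length(hit) > 0) runs[[hit[1]]]
      else runs[[which.max(lengths(runs))]]
    widths <- c(widths, length(run) * sp[1])
    ypos <- c(ypos, ys[j])
  }
  if (length(widths) == 0)
    stop("no coronal slice shows a defect within the search window")
  if (jitter_sd > 0) {
    widths <- .with_seed(seed,
                         pmax(widths + stats::rnorm(length(widths), 0, jitter_sd),
                              1e-6))
  }
  slice_width_series(widths, sp[2], y = ypos)
}

#' Slice-based linear 2D area estimate
#'
#' The clinical approximation: with n coronal slices showing the defect,
#' slice thickness d and per-slice mediolateral widths l_i,
#' \deqn{A = n \cdot d \cdot \frac{\sum_i l_i}{n} = d \sum_i l_i,}
#' i.e. a Riemann sum of the defect's mediolateral extent along the
#' anteroposterior axis. For a floor tilted by \eqn{\theta} about the
#' mediolateral axis this converges to \eqn{\cos\theta} times the intrinsic
#' defect area — the geometric mechanism by which the 2D protocol
#' underestimates tilted or curved defects.
#'
#' @param series a [slice_width_series()].
#' @return estimated area in mm^2, exactly `d * sum(widths)`.
#' @export
area_2d <- function(series) {
  stopifnot(inherits(series, "slice_width_series"))
  series$slice_thickness * sum(series$widths)
}

#' Per-slice width table
#'
#' @param series a [slice_width_series()].
#' @param case_id optional case identifier column.
#' @return data.frame with slice_index, y_mm and width_mm.
#' @export
slice_width_table <- function(series, case_id = NA_character_) {
  stopifnot(inherits(series, "slice_width_series"))
  data.frame(case_id = case_id,
             slice_index = seq_along(series$widths),
             y_mm = if (is.null(series$y)) NA_real_ else series$y,
             width_mm = series$widths)
}
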