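#' Configuration for a full in-silico cohort experiment
#'
#' @param n_cases cohort size.
#' @param seed mandatory integer seed for cohort sampling and noise.
#' @param param_ranges phantom sampling ranges, see [sample_cohort()].
#' @param hu_min bone threshold, HU.
#' @param degree polynomial patch degree.
#' @param grid_resolution patch-area integration resolution, mm.
#' @param output_dir directory for per-case and report files, or `NULL` to
#'   keep everything in memory.
#' @param measure3d further 3D measurement settings, see
#'   [measure3d_config()].
#' @return a named list of class `run_config`.
#' @export
run_config <- function(n_cases = 50, seed, param_ranges = list(),
                       hu_min = 300, degree = 2, grid_resolution = 0.25,
                       output_dir = NULL, measure3d = list()) {
  if (missing(seed)) stop("seed is mandatory for cohort runs")
  m3 <- do.call(measure3d_config,
                utils::modifyList(list(hu_min = hu_min, degree = degree,
                                       grid_resolution = grid_resolution),
                                  measure3d))
  structure(list(n_cases = n_cases, seed = as.integer(seed),
                 param_ranges = param_ranges, hu_min = hu_min,
                 degree = degree, grid_resolution = grid_resolution,
                 output_dir = output_dir, measure3d = m3),
            class = "run_config")
}

#' Measure one case with both techniques
#'
#' Runs the slice-based 2D estimator (per-coronal-slice mediolateral widths
#' on the segmented bone mask) and the surface-based 3D measurement on the
#' same volume.
#'
#' @param volume a [voxel_volume()].
#' @param hint approximate defect centre (mm) or `ground_truth`.
#' @param config a [run_config()] (its `measure3d` part is used) or a
#'   [measure3d_config()].
#' @return list with `a2d`, `a3d` (mm^2) and the `area3d_result` under
#'   `detail`.
#' @export
measure_case <- function(volume, hint, config = run_config(seed = 1L)) {
  m3 <- if (inherits(config, "run_config")) config$measure3d else config
  if (inherits(hint, "ground_truth")) hint <- hint$defect_center
  mask <- largest_component(threshold_bone(volume, m3$hu_min),
                            m3$connectivity)
  sw <- slice_widths(mask, hint = hint,
                     search_radius = m3$search_radius)
  a2d <- area_2d(sw)
  res3 <- area_3d(volume, hint, config = m3)
  list(a2d = a2d, a3d = res3$area, slice_widths = sw, detail = res3)
}

#' Run the full cohort experiment
#'
#' Samples a phantom cohort, rasterizes each case, measures it with both
#' techniques and performs the paired comparison. Per-stage wall-clock
#' timings are logged for interest only. A case whose measurement fails is
#' flagged and excluded; the run aborts if more than 10% of cases fail.
#' Bit-reproducible for a fixed config.
#'
#' @param config a [run_config()].
#' @param verbose print per-case progress.
#' @return list of class `experiment_result`: `result`
#'   (a [paired_cohort_result()]), `cases` (per-case data.frame with truth
#'   and errors), `failed` (case ids and reasons), `manifest`, `report`
#'   (via [cohort_report()]) and `timings`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  specs <- sample_cohort(config$n_cases, config$param_ranges,
                         seed = config$seed)
  manifest <- cohort_manifest(specs)
  rows <- vector("list", length(specs))
  failed <- list()
  timings <- numeric(0)
  for (i in seq_along(specs)) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch({
      ph <- rasterize_phantom(specs[[i]])
      m <- measure_case(ph$volume, ph$truth, config)
      data.frame(case_id = manifest$case_id[i],
                 a2d = m$a2d, a3d = m$a3d,
                 true_area_3d = ph$truth$true_area_3d,
                 projected_area = ph$truth$projected_area,
                 rel_err_3d = (m$a3d - ph$truth$true_area_3d) /
                   ph$truth$true_area_3d,
                 n_slices = length(m$slice_widths$widths))
    }, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    timings <- c(timings, dt)
    if (inherits(out, "error")) {
      failed[[length(failed) + 1]] <- list(case_id = manifest$case_id[i],
                                           reason = conditionMessage(out))
      if (verbose) message(manifest$case_id[i], " FAILED: ",
                           conditionMessage(out))
    } else {
      rows[[i]] <- out
      if (verbose) message(sprintf("%s  a2d %7.1f  a3d %7.1f  truth %7.1f  (%.1fs)",
                                   out$case_id, out$a2d, out$a3d,
                                   out$true_area_3d, dt))
    }
  }
  cases <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (length(failed) > 0.1 * length(specs))
    stop("experiment failed: ", length(failed), " of ", length(specs),
         " cases aborted (first: ", failed[[1]]$reason, ")")
  result <- paired_cohort_result(cases)
  report <- cohort_report(result)
  out <- structure(list(result = result, cases = cases, failed = failed,
                        manifest = manifest, report = report,
                        timings = timings, config = config),
                   class = "experiment_result")
  if (!is.null(config$output_dir)) .write_experiment(out, config$output_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment: %d cases measured, %d failed, %.1f s total\n",
              nrow(x$cases), length(x$failed), sum(x$timings)))
  print(x$result)
  invisible(x)
}

# write per-case CSV, summary table, plot segments and a machine-readable
# manifest linking outputs to cases
.write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cases = "cases.csv", table = "summary_table.csv",
             segments = "paired_segments.csv", manifest = "manifest.csv",
             failed = "failed_cases.csv")
  utils::write.csv(x$cases, file.path(dir, paths["cases"]), row.names = FALSE)
  utils::write.csv(x$report$table, file.path(dir, paths["table"]),
                   row.names = FALSE)
  utils::write.csv(x$report$segments, file.path(dir, paths["segments"]),
                   row.names = FALSE)
  utils::write.csv(x$manifest, file.path(dir, paths["manifest"]),
                   row.names = FALSE)
  fdf <- if (length(x$failed) > 0)
    data.frame(case_id = vapply(x$failed, `[[`, "", "case_id"),
               reason = vapply(x$failed, `[[`, "", "reason"))
  else data.frame(case_id = character(0), reason = character(0))
  utils::write.csv(fdf, file.path(dir, paths["failed"]), row.names = FALSE)
  invisible(file.path(dir, paths))
}
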