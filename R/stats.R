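#' Summary statistics for a set of defect areas
#'
#' Mean (MV), median (MED), sample standard deviation (n-1 denominator),
#' minimum and maximum.
#'
#' @param areas numeric vector of areas, mm^2 (n >= 2 for the SD).
#' @return named list with `mean`, `median`, `sd`, `min`, `max`, `n`.
#' @export
summarize_areas <- function(areas) {
  areas <- as.numeric(areas)
  if (length(areas) == 0) stop("empty input")
  if (any(!is.finite(areas))) stop("non-finite areas")
  list(mean = mean(areas), median = stats::median(areas),
       sd = if (length(areas) >= 2) stats::sd(areas) else NA_real_,
       min = min(areas), max = max(areas), n = length(areas))
}

#' Per-case fold ratios between 3D and 2D measurements
#'
#' `fold_i = a3d_i / a2d_i` for each case, with summary statistics of the
#' fold distribution. The mean of per-case ratios is not the ratio of means;
#' both are returned under distinct names.
#'
#' @param pairs data.frame or matrix with columns `a2d` and `a3d` (mm^2),
#'   all `a2d > 0`.
#' @return list with `fold` (per-case vector), `summary`
#'   (via [summarize_areas()] on the folds) and `ratio_of_means`.
#' @export
fold_stats <- function(pairs) {
  p <- .as_pairs(pairs)
  if (any(p$a2d <= 0)) stop("fold undefined: some a2d <= 0")
  fold <- p$a3d / p$a2d
  list(fold = fold,
       summary = summarize_areas(fold),
       ratio_of_means = mean(p$a3d) / mean(p$a2d))
}

.as_pairs <- function(pairs) {
  p <- as.data.frame(pairs)
  if (!all(c("a2d", "a3d") %in% names(p))) {
    if (ncol(p) < 2) stop("pairs needs columns a2d and a3d")
    names(p)[1:2] <- c("a2d", "a3d")
  }
  if (nrow(p) == 0) stop("empty pairs")
  p
}

# exact null distribution of the positive rank sum W+ given the (possibly
# tied, midranked) absolute-difference ranks: generating-function
# convolution of prod_i (1 + x^(2 r_i)) / 2^n over doubled ranks, so tied
# midranks (.5 steps) stay integral
.signed_rank_distribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  probs <- c(1)                     # P(2*W+ = 0..)
  for (r in r2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) + shifted
  }
  probs / 2^length(ranks)
}

#' Paired nonparametric comparison of 2D and 3D areas
#'
#' The default is the Wilcoxon signed-rank test, the standard paired
#' analog of the Mann-Whitney U test: absolute within-pair differences are
#' ranked (midranks for ties, zero differences dropped) and the smaller of
#' the positive/negative rank sums is the statistic. Exact two-sided
#' p-values come from the generating-function convolution of the rank set
#' (equivalent to enumerating all 2^n sign assignments); the normal
#' approximation applies a tie-corrected variance and a 0.5 continuity
#' correction. An unpaired Mann-Whitney U is available behind
#' `method = "mann_whitney_u"` for completeness.
#'
#' @param pairs data.frame/matrix with columns `a2d`, `a3d`.
#' @param method `"wilcoxon_signed_rank"` (paired; default) or
#'   `"mann_whitney_u"` (unpaired).
#' @param mode `"auto"` (exact up to n = 25 without ties), `"exact"` or
#'   `"normal_approx"`. Exact mode with ties uses the tie-conditional
#'   midrank distribution.
#' @return list with `test_name`, `statistic` (W = min(W+, W-) for the
#'   signed-rank test), `p_value`, `n_effective` and `mode`.
#' @export
paired_test <- function(pairs,
                        method = c("wilcoxon_signed_rank", "mann_whitney_u"),
                        mode = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  p <- .as_pairs(pairs)

  if (method == "mann_whitney_u") {
    wt <- stats::wilcox.test(p$a3d, p$a2d, paired = FALSE,
                             exact = (mode == "exact"), correct = TRUE)
    return(list(test_name = "Mann-Whitney U (unpaired)",
                statistic = unname(wt$statistic), p_value = wt$p.value,
                n_effective = nrow(p), mode = mode))
  }

  d <- p$a3d - p$a2d
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero: test undefined")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)

  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = n <= 25)
  if (use_exact) {
    if (mode == "exact" && n > 25)
      stop("exact mode is limited to n <= 25")
    probs <- .signed_rank_distribution(r)    # P(2*W+ = 0, 0.5, 1, ...)
    k <- as.integer(round(2 * w_pos))
    p_le <- sum(probs[seq_len(k + 1)])
    p_ge <- sum(probs[(k + 1):length(probs)])
    pval <- min(1, 2 * min(p_le, p_ge))
    used <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    pval <- 2 * stats::pnorm(-abs(z))
    used <- "normal_approx"
  }
  list(test_name = "Wilcoxon signed-rank (paired)",
       statistic = w, p_value = pval, n_effective = n, mode = used)
}

#' Count cases where the 3D measurement is larger, smaller, or tied
#'
#' @param pairs data.frame/matrix with columns `a2d`, `a3d`.
#' @param tol tie tolerance in mm^2.
#' @return named list `n_3d_larger`, `n_2d_larger`, `n_ties`; the three
#'   always sum to the number of cases.
#' @export
count_comparison <- function(pairs, tol = 1e-9) {
  p <- .as_pairs(pairs)
  d <- p$a3d - p$a2d
  list(n_3d_larger = sum(d > tol),
       n_2d_larger = sum(d < -tol),
       n_ties = sum(abs(d) <= tol))
}

#' Assemble a paired cohort comparison result
#'
#' @param pairs data.frame with columns `case_id` (optional), `a2d`, `a3d`.
#' @param method,mode passed to [paired_test()].
#' @return object of class `paired_cohort_result`: per-case table with fold
#'   ratios, per-method summaries, comparison counts and the paired test.
#' @export
paired_cohort_result <- function(pairs,
                                 method = "wilcoxon_signed_rank",
                                 mode = "auto") {
  p <- .as_pairs(pairs)
  if (is.null(p$case_id)) p$case_id <- sprintf("case_%03d", seq_len(nrow(p)))
  fs <- fold_stats(p)
  p$fold <- fs$fold
  structure(list(
    cases = p[, c("case_id", "a2d", "a3d", "fold")],
    summary_2d = summarize_areas(p$a2d),
    summary_3d = summarize_areas(p$a3d),
    summary_fold = fs$summary,
    ratio_of_means = fs$ratio_of_means,
    counts = count_comparison(p),
    test = paired_test(p, method = method, mode = mode)
  ), class = "paired_cohort_result")
}

#' @export
print.paired_cohort_result <- function(x, ...) {
  cat(sprintf(
    "paired cohort, n = %d\n  2D: mean %.2f, median %.2f mm^2\n  3D: mean %.2f, median %.2f mm^2\n  mean fold (3D/2D) %.2f; 3D larger in %d, smaller in %d, ties %d\n  %s: W = %.1f, p = %.3g (%s)\n",
    nrow(x$cases), x$summary_2d$mean, x$summary_2d$median,
    x$summary_3d$mean, x$summary_3d$median, x$summary_fold$mean,
    x$counts$n_3d_larger, x$counts$n_2d_larger, x$counts$n_ties,
    x$test$test_name, x$test$statistic, x$test$p_value, x$test$mode))
  invisible(x)
}

#' Cohort report table and paired-lines plot data
#'
#' Produces the summary table of the cohort comparison (rows Mean, Median,
#' SD, Minimum, Maximum; columns for the 2D and 3D methods and the
#' per-case fold ratio) plus one line segment per case for a paired-lines
#' plot.
#'
#' @param result a [paired_cohort_result()].
#' @return list with `table` (data.frame) and `segments` (data.frame with
#'   one row per case: `case_id`, `a2d`, `a3d`).
#' @export
cohort_report <- function(result) {
  stopifnot(inherits(result, "paired_cohort_result"))
  if (nrow(result$cases) == 0) stop("empty result")
  s2 <- result$summary_2d
  s3 <- result$summary_3d
  sf <- result$summary_fold
  tab <- data.frame(
    statistic = c("Mean", "Median", "SD", "Minimum", "Maximum"),
    area_2d = c(s2$mean, s2$median, s2$sd, s2$min, s2$max),
    area_3d = c(s3$mean, s3$median, s3$sd, s3$min, s3$max),
    fold = c(sf$mean, sf$median, sf$sd, sf$min, sf$max)
  )
  segments <- result$cases[, c("case_id", "a2d", "a3d")]
  list(table = tab, segments = segments,
       p_value = result$test$p_value)
}
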