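# Univariate posterior summaries: moments, HPD intervals, kernel
# density estimates, histograms, boxplot/violin data, frequency tables.

#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted samples containing the
#' requested posterior mass. The window length is
#' `m = max(1, round(proportion * n))`; among all `n - m + 1`
#' contiguous windows the narrowest is returned, ties broken by the
#' lowest start index.
#'
#' @param values Numeric samples, n >= 2.
#' @param proportion Posterior mass in (0, 1); default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(values, proportion = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 samples for an HPD interval",
                  call. = FALSE)
  stopifnot(proportion > 0, proportion < 1)
  s <- sort(values)
  m <- max(1L, as.integer(floor(proportion * n + 0.5)))
  widths <- s[m:n] - s[1:(n - m + 1L)]
  i <- which.min(widths)  # first minimum = lowest start index
  c(s[i], s[i + m - 1L])
}

#' Summarize a numeric trace
#'
#' The standard per-parameter summary: sample mean, standard deviation
#' (n - 1 denominator), autocorrelation-corrected standard error of the
#' mean, median, HPD interval, range, ACT and ESS.
#'
#' @param trace A `tk_trace` of type real/integer, or a numeric vector.
#' @param step_size Sampling interval in states (ignored when a
#'   combined `tk_trace` carries per-component intervals).
#' @param proportion HPD mass, default 0.95.
#' @return A `trace_summary` list.
#' @export
summarize_trace <- function(trace, step_size = 1, proportion = 0.95) {
  if (inherits(trace, "tk_trace")) {
    if (trace$type == "categorical") {
      stop(sprintf(
        "trace '%s' is categorical; use frequency_table() for discrete summaries",
        trace$name), call. = FALSE)
    }
    values <- trace$values
    name <- trace$name
  } else {
    values <- as.numeric(trace)
    trace <- values
    name <- NA_character_
  }
  diag <- if (length(values) >= 4) {
    ess_diagnostic(trace, step_size)
  } else {
    # too short for an autocorrelation estimate: fall back to the
    # uncorrected standard error and leave ACT/ESS undetermined
    list(act = NA_real_, ess = NA_real_,
         stderr_of_mean = stats::sd(values) / sqrt(length(values)),
         flag = NA_character_, degenerate = FALSE)
  }
  hpd <- hpd_interval(values, proportion)
  structure(
    list(name = name,
         mean = mean(values),
         stdev = stats::sd(values),
         stderr_of_mean = diag$stderr_of_mean,
         median = stats::median(values),
         hpd_lower = hpd[1], hpd_upper = hpd[2],
         hpd_proportion = proportion,
         min = min(values), max = max(values),
         act = diag$act, ess = diag$ess, flag = diag$flag,
         degenerate = diag$degenerate,
         n = length(values)),
    class = "trace_summary"
  )
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf("<trace_summary%s> n=%d\n",
              if (is.na(x$name)) "" else sprintf(" '%s'", x$name), x$n))
  cat(sprintf("  mean %.6g (se %.6g), sd %.6g, median %.6g\n",
              x$mean, x$stderr_of_mean, x$stdev, x$median))
  cat(sprintf("  %d%% HPD [%.6g, %.6g], ACT %.6g, ESS %.6g (%s)\n",
              round(100 * x$hpd_proportion), x$hpd_lower, x$hpd_upper,
              x$act, x$ess, x$flag))
  invisible(x)
}

silverman_bandwidth <- function(values) {
  s <- stats::sd(values)
  iqr <- diff(stats::quantile(values, c(0.25, 0.75), names = FALSE,
                              type = 7))
  cand <- c(s, iqr / 1.34)
  cand <- cand[cand > 0]
  if (length(cand) == 0) {
    stop("all values identical: no finite bandwidth exists", call. = FALSE)
  }
  0.9 * min(cand) * length(values)^(-1 / 5)
}

#' Gaussian kernel density estimate of a posterior marginal
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth
#' `h = 0.9 * min(s, IQR/1.34) * n^(-1/5)` by default, evaluated on an
#' equally spaced grid spanning `[min - 3h, max + 3h]`. An optional
#' lower-bound reflection handles strictly positive parameters.
#'
#' @param values Numeric samples (n >= 3, at least two distinct).
#' @param bandwidth Positive bandwidth, or `"auto"` for Silverman.
#' @param grid_points Number of grid points (default 512).
#' @param reflect_lower Optional lower bound; when given, mass below it
#'   is reflected back into the support.
#' @return A `density_estimate` with `grid`, `density`, `bandwidth`.
#' @export
kde_estimate <- function(values, bandwidth = "auto", grid_points = 512,
                         reflect_lower = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 samples for a density estimate",
                  call. = FALSE)
  if (length(unique(values)) < 2) {
    stop("all values identical: degenerate distribution has no density",
         call. = FALSE)
  }
  h <- if (identical(bandwidth, "auto")) silverman_bandwidth(values)
       else as.numeric(bandwidth)
  stopifnot(h > 0)
  lo <- min(values) - 3 * h
  hi <- max(values) + 3 * h
  if (is.null(reflect_lower)) {
    d <- stats::density(values, bw = h, kernel = "gaussian",
                        from = lo, to = hi, n = grid_points)
    out <- list(grid = d$x, density = d$y, bandwidth = h,
                mirrored = FALSE)
  } else {
    lo <- max(lo, reflect_lower)
    aug <- c(values, 2 * reflect_lower - values)
    d <- stats::density(aug, bw = h, kernel = "gaussian",
                        from = lo, to = hi, n = grid_points)
    out <- list(grid = d$x, density = 2 * d$y, bandwidth = h,
                mirrored = FALSE)
  }
  structure(out, class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %d grid points on [%.6g, %.6g], bw %.6g%s\n",
              length(x$grid), min(x$grid), max(x$grid), x$bandwidth,
              if (isTRUE(x$mirrored)) " (violin)" else ""))
  invisible(x)
}

#' Histogram of a numeric trace
#'
#' Equal-width bins over the sample range. The automatic bin count is
#' `max(10, ceiling(sqrt(n)))`, capped at 100. The right-most bin is
#' closed, so every sample is counted exactly once. A single distinct
#' value yields one bin holding all samples.
#'
#' @param values Numeric samples.
#' @param bins Bin count, or `"auto"`.
#' @return List with `edges` (length bins + 1) and `counts`.
#' @export
trace_histogram <- function(values, bins = "auto") {
  values <- as.numeric(values)
  n <- length(values)
  if (identical(bins, "auto")) {
    bins <- min(100L, max(10L, as.integer(ceiling(sqrt(n)))))
  }
  bins <- as.integer(bins)
  stopifnot(bins >= 1)
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    return(list(edges = c(lo - 0.5, hi + 0.5), counts = n))
  }
  edges <- seq(lo, hi, length.out = bins + 1L)
  w <- (hi - lo) / bins
  idx <- pmin(bins, as.integer(floor((values - lo) / w)) + 1L)
  list(edges = edges, counts = tabulate(idx, nbins = bins))
}

#' Frequency table of a discrete trace
#'
#' Levels are sorted numerically for integer traces and lexically for
#' categorical ones; probabilities are empirical proportions.
#'
#' @param trace A `tk_trace` of type integer/categorical, or a vector
#'   with `type` supplied.
#' @param type Required when `trace` is a bare vector.
#' @return A `frequency_table` with `levels`, `counts`, `probabilities`,
#'   `n`.
#' @export
frequency_table <- function(trace, type = NULL) {
  if (inherits(trace, "tk_trace")) {
    type <- trace$type
    values <- trace$values
  } else {
    if (is.null(type)) stop("supply type for a bare vector", call. = FALSE)
    values <- trace
  }
  if (type == "real") {
    stop("frequency tables are for integer or categorical traces; use kde_estimate()/trace_histogram() for real traces",
         call. = FALSE)
  }
  if (type == "integer") {
    lev <- sort(unique(as.numeric(values)))
    counts <- vapply(lev, function(l) sum(values == l), numeric(1))
  } else {
    lev <- sort(unique(as.character(values)))
    counts <- vapply(lev, function(l) sum(values == l), numeric(1))
  }
  counts <- unname(counts)
  structure(
    list(levels = lev, counts = as.integer(counts),
         probabilities = counts / length(values), n = length(values)),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> n=%d\n", x$n))
  print(stats::setNames(round(x$probabilities, 4), x$levels))
  invisible(x)
}

#' Boxplot statistics for a numeric trace
#'
#' Quartiles by linear interpolation between order statistics
#' (quantile type 7); whiskers extend to the most extreme data point
#' within 1.5 IQR of the box; points beyond are outliers.
#'
#' @param values Numeric samples, n >= 4.
#' @return A `boxplot_stats` list: `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
boxplot_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) {
    stop("need at least 4 samples for boxplot statistics", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  in_fence <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  structure(
    list(q1 = q[1], median = q[2], q3 = q[3],
         whisker_low = min(values[in_fence]),
         whisker_high = max(values[in_fence]),
         outliers = sort(values[!in_fence])),
    class = "boxplot_stats"
  )
}

#' Violin-plot data for a numeric trace
#'
#' The kernel density estimate of [kde_estimate()] tagged for mirrored
#' rendering.
#'
#' @inheritParams kde_estimate
#' @return A `density_estimate` with `mirrored = TRUE`.
#' @export
violin_data <- function(values, bandwidth = "auto", grid_points = 512) {
  d <- kde_estimate(values, bandwidth, grid_points)
  d$mirrored <- TRUE
  d
}
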