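# Joint-marginal summaries: joint probability tables for discrete
# pairs (bubble-chart data), Pearson correlation matrices with ellipse
# glyph parameters, scatter data, and conditional posterior summaries
# including indicator conditioning under BSSVS.

check_aligned <- function(a, b) {
  if (a$n != b$n) {
    stop(sprintf("traces '%s' (n=%d) and '%s' (n=%d) are not aligned",
                 a$name, a$n, b$name, b$n), call. = FALSE)
  }
}

as_tk_trace <- function(x, name = "x") {
  if (inherits(x, "tk_trace")) return(x)
  new_trace(name, infer_trace_type(as.character(x)),
            if (is.numeric(x)) x else as.character(x))
}

#' Joint probability table of two discrete traces
#'
#' Empirical joint distribution of two integer or categorical traces
#' sampled at the same states: the data behind a bubble chart where
#' circle area is proportional to the joint probability and cells at or
#' above a nominal threshold get a background tile.
#'
#' @param a,b Discrete `tk_trace` objects (or vectors) of equal length.
#' @param tile_threshold Probability threshold for the tile mask,
#'   default 0.01.
#' @return A `joint_table` with `levels_a`, `levels_b`, `joint_prob`,
#'   `counts`, `tile_mask`, `n`.
#' @export
joint_probability <- function(a, b, tile_threshold = 0.01) {
  a <- as_tk_trace(a, "a"); b <- as_tk_trace(b, "b")
  for (tr in list(a, b)) {
    if (!is_discrete(tr)) {
      stop(sprintf("trace '%s' is continuous; joint tables need discrete traces",
                   tr$name), call. = FALSE)
    }
  }
  check_aligned(a, b)
  lev_a <- frequency_table(a)$levels
  lev_b <- frequency_table(b)$levels
  counts <- table(factor(a$values, levels = lev_a),
                  factor(b$values, levels = lev_b))
  counts <- matrix(as.integer(counts), nrow = length(lev_a),
                   dimnames = list(as.character(lev_a), as.character(lev_b)))
  p <- counts / a$n
  structure(
    list(levels_a = lev_a, levels_b = lev_b,
         joint_prob = p, counts = counts,
         tile_threshold = tile_threshold,
         tile_mask = p >= tile_threshold,
         n = a$n),
    class = "joint_table"
  )
}

#' @export
print.joint_table <- function(x, ...) {
  cat(sprintf("<joint_table> %d x %d levels, n=%d, tile threshold %g\n",
              length(x$levels_a), length(x$levels_b), x$n,
              x$tile_threshold))
  print(round(x$joint_prob, 4))
  invisible(x)
}

ellipse_params <- function(r) {
  list(semi_major = sqrt(1 + abs(r)),
       semi_minor = sqrt(1 - abs(r)),
       orientation = if (r >= 0) 45 else -45)
}

#' Pearson correlation matrix with ellipse glyph parameters
#'
#' Pairwise Pearson correlations of two or more continuous traces on
#' aligned samples, plus the ellipse parameters of the standard
#' correlogram glyph: semi-axes `sqrt(1 + |r|)` and `sqrt(1 - |r|)` at
#' +45 degrees for positive and -45 degrees for negative correlation,
#' so no correlation draws a circle and perfect (anti)correlation a
#' line.
#'
#' @param traces List of >= 2 continuous `tk_trace` objects (or numeric
#'   vectors) of equal length n >= 3.
#' @return A `correlation_matrix` with `names`, `r` and `ellipses`.
#' @export
pearson_matrix <- function(traces) {
  stopifnot(length(traces) >= 2)
  traces <- lapply(seq_along(traces), function(i)
    as_tk_trace(traces[[i]],
                if (!is.null(names(traces))) names(traces)[i]
                else sprintf("trace%d", i)))
  n <- traces[[1]]$n
  stopifnot(n >= 3)
  for (tr in traces) {
    if (tr$type == "categorical") {
      stop(sprintf("trace '%s' is categorical; correlations need numeric traces",
                   tr$name), call. = FALSE)
    }
    if (tr$n != n) {
      stop(sprintf("trace '%s' is not aligned (n=%d vs %d)",
                   tr$name, tr$n, n), call. = FALSE)
    }
    if (stats::sd(tr$values) == 0) {
      stop(sprintf("trace '%s' has zero variance; correlation undefined",
                   tr$name), call. = FALSE)
    }
  }
  nm <- vapply(traces, `[[`, character(1), "name")
  m <- vapply(traces, `[[`, numeric(n), "values")
  r <- stats::cor(m)
  dimnames(r) <- list(nm, nm)
  k <- length(nm)
  ell <- vector("list", 0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      e <- ellipse_params(r[i, j])
      e$pair <- c(nm[i], nm[j])
      ell[[length(ell) + 1L]] <- e
    }
  }
  structure(list(names = nm, r = r, ellipses = ell),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d traces\n", length(x$names)))
  print(round(x$r, 3))
  invisible(x)
}

#' Aligned scatter data for two continuous traces
#'
#' Passes the aligned sample pairs through unmodified with the Pearson
#' correlation attached.
#'
#' @param a,b Continuous `tk_trace` objects (or numeric vectors) of
#'   equal length.
#' @return Data frame with columns named after the traces; attribute
#'   `r` holds the Pearson correlation.
#' @export
scatter_data <- function(a, b) {
  a <- as_tk_trace(a, "a"); b <- as_tk_trace(b, "b")
  check_aligned(a, b)
  out <- stats::setNames(data.frame(a$values, b$values),
                         make.unique(c(a$name, b$name)))
  attr(out, "r") <- stats::cor(a$values, b$values)
  out
}

summarize_or_count <- function(values, step_size) {
  if (length(values) >= 2) {
    s <- summarize_trace(values, step_size)
    s$insufficient <- FALSE
    s
  } else {
    structure(list(n = length(values),
                   mean = if (length(values) == 1) values else NA_real_,
                   insufficient = TRUE),
              class = "trace_summary")
  }
}

#' Conditional posterior summary of a continuous trace
#'
#' Summarizes a continuous parameter restricted to the samples at each
#' unique level of a discrete parameter sampled alongside it — the data
#' behind side-by-side violin/boxplots of a conditional posterior.
#' Levels observed fewer than twice report counts only and are flagged.
#'
#' @param x Continuous `tk_trace` (or numeric vector).
#' @param g Discrete `tk_trace` (or vector) of equal length.
#' @param step_size Sampling interval for ESS within each slice.
#' @return A `conditional_summary`: `levels`, `per_level_n`, and a
#'   `per_level` list each holding `summary`, `boxplot`, `violin`.
#' @export
conditional_summary <- function(x, g, step_size = 1) {
  x <- as_tk_trace(x, "x"); g <- as_tk_trace(g, "g")
  if (!is_numeric_trace(x)) {
    stop(sprintf("trace '%s' must be continuous", x$name), call. = FALSE)
  }
  if (!is_discrete(g)) {
    stop(sprintf("trace '%s' must be discrete", g$name), call. = FALSE)
  }
  check_aligned(x, g)
  ft <- frequency_table(g)
  per_level <- lapply(ft$levels, function(lev) {
    vals <- x$values[g$values == lev]
    out <- list(summary = summarize_or_count(vals, step_size),
                boxplot = NULL, violin = NULL)
    if (length(vals) >= 4) out$boxplot <- boxplot_stats(vals)
    if (length(vals) >= 3 && length(unique(vals)) >= 2) {
      out$violin <- violin_data(vals)
    }
    out
  })
  names(per_level) <- as.character(ft$levels)
  structure(
    list(levels = ft$levels, per_level_n = ft$counts,
         per_level = per_level, n = x$n),
    class = "conditional_summary"
  )
}

#' @export
print.conditional_summary <- function(x, ...) {
  cat(sprintf("<conditional_summary> %d levels, n=%d\n",
              length(x$levels), x$n))
  for (i in seq_along(x$levels)) {
    s <- x$per_level[[i]]$summary
    if (isTRUE(s$insufficient)) {
      cat(sprintf("  %s: n=%d (too few samples to summarize)\n",
                  x$levels[i], x$per_level_n[i]))
    } else {
      cat(sprintf("  %s: n=%d mean %.6g [%.6g, %.6g]\n",
                  x$levels[i], x$per_level_n[i], s$mean,
                  s$hpd_lower, s$hpd_upper))
    }
  }
  invisible(x)
}

#' Indicator-conditioned rate summary (BSSVS)
#'
#' Under Bayesian stochastic search variable selection a rate parameter
#' only enters the likelihood in states where its binary indicator
#' equals one, so its posterior summary must be restricted to exactly
#' those samples. Returns the conditional summary together with the
#' posterior inclusion probability P(indicator = 1).
#'
#' @param rate Continuous `tk_trace` (or numeric vector).
#' @param indicator Integer `tk_trace` (or vector) with values in
#'   \{0, 1\}, aligned with `rate`.
#' @param step_size Sampling interval.
#' @return A `trace_summary` of the conditioned rate, with an extra
#'   `inclusion_prob` field.
#' @export
bssvs_rate_summary <- function(rate, indicator, step_size = 1) {
  rate <- as_tk_trace(rate, "rate")
  indicator <- as_tk_trace(indicator, "indicator")
  check_aligned(rate, indicator)
  iv <- indicator$values
  if (indicator$type == "categorical" || !all(iv %in% c(0, 1))) {
    stop(sprintf("trace '%s' is not a binary 0/1 indicator",
                 indicator$name), call. = FALSE)
  }
  on <- iv == 1
  if (sum(on) < 2) {
    stop(sprintf(
      "indicator '%s' is 1 in %d sample(s); no support to summarize the rate",
      indicator$name, sum(on)), call. = FALSE)
  }
  s <- summarize_trace(rate$values[on], step_size)
  s$name <- rate$name
  s$inclusion_prob <- mean(on)
  s
}
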