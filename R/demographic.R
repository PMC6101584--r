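# Demographic trajectory reconstruction from posterior trace columns.
#
# Time convention: t = 0 at the most recent sample, increasing into the
# past. A growth rate r > 0 means the population grows toward the
# present, so looking backwards N(t) = N0 * exp(-r t) for exponential
# growth. The logistic model uses the shape parameterization
# N(t) = N0 (1 + c) / (1 + c e^{r t}) with c > 0. The skygrid is
# piecewise constant on K equal bins of [0, T]: N(t) = exp(theta_j) for
# t in [t_{j-1}, t_j) with t_j = j T / K, and exp(theta_K) beyond the
# cutoff T.

#' Specify a demographic model over trace columns
#'
#' Maps the parameters of a coalescent demographic model to named trace
#' columns so that a population-size trajectory can be evaluated for
#' every posterior sample.
#'
#' @param kind `"constant"`, `"exponential"`, `"logistic"` or
#'   `"skygrid"`.
#' @param columns Named character vector mapping model parameters to
#'   trace names: `N0` (constant); `N0`, `r` (exponential); `N0`, `r`,
#'   `c` (logistic). Ignored for skygrid.
#' @param theta_columns For skygrid: ordered character vector of the
#'   log-population-size columns theta_1..theta_K (most recent bin
#'   first). See [skygrid_columns()].
#' @param cutoff For skygrid: the grid cutoff T > 0 (an analysis
#'   setting of the original run, not always logged).
#' @return A `demographic_model`.
#' @export
demographic_model <- function(kind = c("constant", "exponential",
                                       "logistic", "skygrid"),
                              columns = NULL, theta_columns = NULL,
                              cutoff = NULL) {
  kind <- match.arg(kind)
  required <- switch(kind,
    constant = "N0",
    exponential = c("N0", "r"),
    logistic = c("N0", "r", "c"),
    skygrid = character(0))
  if (kind == "skygrid") {
    if (is.null(theta_columns) || length(theta_columns) < 1) {
      stop("skygrid needs at least one log-population-size column",
           call. = FALSE)
    }
    if (is.null(cutoff) || cutoff <= 0) {
      stop("skygrid needs a positive cutoff T", call. = FALSE)
    }
  } else {
    missing <- setdiff(required, names(columns))
    if (length(missing) > 0) {
      stop(sprintf("model '%s' needs column mappings for: %s",
                   kind, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(kind = kind, columns = columns,
                 theta_columns = theta_columns, cutoff = cutoff),
            class = "demographic_model")
}

#' Discover skygrid columns by name prefix
#'
#' Finds the log-population-size columns of a skygrid analysis by a
#' name prefix and orders them by their trailing integer index.
#'
#' @param tf A `trace_file`.
#' @param prefix Column-name prefix (e.g. `"skygrid.logPopSize"`).
#' @return Ordered character vector of column names.
#' @export
skygrid_columns <- function(tf, prefix) {
  nm <- trace_names(tf)
  hits <- nm[startsWith(nm, prefix)]
  if (length(hits) == 0) {
    stop(sprintf("no columns matching prefix '%s'", prefix), call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(sub(".*?(\\d+)$", "\\1", hits,
                                         perl = TRUE)))
  if (anyNA(idx)) {
    stop(sprintf("columns matching '%s' lack trailing integer indices",
                 prefix), call. = FALSE)
  }
  hits[order(idx)]
}

#' Effective population size at given times for one posterior sample
#'
#' Evaluates the demographic function N(t) of one posterior draw at one
#' or more times before the present.
#'
#' @param model A `demographic_model`.
#' @param params Named list/vector of parameter values for this draw:
#'   `N0` (and `r`, `c`) for parametric models, or `theta` (vector of
#'   K log sizes) for skygrid.
#' @param t Non-negative time(s) before the most recent sample.
#' @return N(t), same length as `t`; always positive.
#' @export
pop_size_at <- function(model, params, t) {
  stopifnot(inherits(model, "demographic_model"), all(t >= 0))
  switch(model$kind,
    constant = {
      n0 <- params[["N0"]]
      if (!is.finite(n0) || n0 <= 0) {
        stop("N0 must be positive and finite", call. = FALSE)
      }
      rep(n0, length(t))
    },
    exponential = {
      n0 <- params[["N0"]]; r <- params[["r"]]
      if (!is.finite(n0) || n0 <= 0) {
        stop("N0 must be positive and finite", call. = FALSE)
      }
      n0 * exp(-r * t)
    },
    logistic = {
      n0 <- params[["N0"]]; r <- params[["r"]]; cc <- params[["c"]]
      if (!is.finite(n0) || n0 <= 0) {
        stop("N0 must be positive and finite", call. = FALSE)
      }
      if (!is.finite(cc) || cc <= 0) {
        stop("logistic shape c must be positive and finite", call. = FALSE)
      }
      n0 * (1 + cc) / (1 + cc * exp(r * t))
    },
    skygrid = {
      theta <- params[["theta"]]
      K <- length(theta)
      bin <- pmin(K, floor(t * K / model$cutoff) + 1)
      exp(theta[bin])
    })
}

#' Reconstruct a demographic trajectory from posterior samples
#'
#' Evaluates N(t) for every retained posterior sample on a regular time
#' grid and summarizes each time point across samples by the median and
#' an HPD interval, giving the familiar population-size-through-time
#' envelope plot. The HPD is computed on the natural scale by default;
#' `scale = "log"` computes it on log N and back-transforms (HPD
#' intervals are not transform-invariant).
#'
#' @param tf A `trace_file` (post burn-in n >= 10).
#' @param model A `demographic_model` whose mapped columns exist in
#'   `tf`.
#' @param grid_points Number of time points (default 100).
#' @param t_max Largest time; defaults to the skygrid cutoff for
#'   skygrid models (required otherwise).
#' @param proportion HPD mass, default 0.95.
#' @param scale `"natural"` or `"log"` for the median/HPD summary.
#' @param keep_samples Keep the full n-by-grid matrix of per-sample
#'   trajectories in the result? Default `FALSE`.
#' @return A `trajectory_summary`: `times`, `median`, `hpd_lower`,
#'   `hpd_upper`, and optionally `per_sample_matrix`.
#' @export
reconstruct_trajectory <- function(tf, model, grid_points = 100,
                                   t_max = NULL, proportion = 0.95,
                                   scale = c("natural", "log"),
                                   keep_samples = FALSE) {
  stopifnot(inherits(model, "demographic_model"))
  scale <- match.arg(scale)
  if (is.null(t_max)) {
    if (model$kind == "skygrid") t_max <- model$cutoff
    else stop("t_max is required for parametric models", call. = FALSE)
  }
  stopifnot(t_max > 0, grid_points >= 2)

  mapped <- if (model$kind == "skygrid") model$theta_columns
            else unname(model$columns)
  missing <- setdiff(mapped, trace_names(tf))
  if (length(missing) > 0) {
    stop(sprintf("mapped column(s) not in trace file: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (cn in mapped) {
    tr <- get_trace(tf, cn)
    if (!is_numeric_trace(tr)) {
      stop(sprintf("mapped column '%s' must be numeric", cn),
           call. = FALSE)
    }
  }
  par_mat <- vapply(mapped, function(cn) get_trace(tf, cn)$values,
                    numeric(n_samples(tf)))
  n <- nrow(par_mat)
  if (n < 10) {
    stop(sprintf("need at least 10 post-burn-in samples (have %d)", n),
         call. = FALSE)
  }

  times <- seq(0, t_max, length.out = grid_points)
  traj <- matrix(NA_real_, nrow = n, ncol = grid_points)
  for (i in seq_len(n)) {
    params <- if (model$kind == "skygrid") list(theta = par_mat[i, ])
              else as.list(stats::setNames(par_mat[i, ], names(model$columns)))
    traj[i, ] <- pop_size_at(model, params, times)
  }

  summ_mat <- if (scale == "log") log(traj) else traj
  med <- apply(summ_mat, 2, stats::median)
  hpd <- apply(summ_mat, 2, hpd_interval, proportion = proportion)
  if (scale == "log") {
    med <- exp(med); hpd <- exp(hpd)
  }
  structure(
    list(times = times, median = med,
         hpd_lower = hpd[1, ], hpd_upper = hpd[2, ],
         hpd_proportion = proportion, scale = scale, n = n,
         per_sample_matrix = if (keep_samples) traj else NULL),
    class = "trajectory_summary"
  )
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf(
    "<trajectory_summary> %d time points on [0, %.6g], %d samples, %s-scale HPD\n",
    length(x$times), max(x$times), x$n, x$scale))
  cat(sprintf("  N(0) median %.6g [%.6g, %.6g]\n",
              x$median[1], x$hpd_lower[1], x$hpd_upper[1]))
  invisible(x)
}

#' Export a trajectory summary as TSV
#'
#' Writes columns `time`, `median`, `hpd_lower`, `hpd_upper`.
#'
#' @param ts A `trajectory_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_summary"))
  df <- data.frame(time = ts$times, median = ts$median,
                   hpd_lower = ts$hpd_lower, hpd_upper = ts$hpd_upper)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
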