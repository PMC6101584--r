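# Autocorrelation time, effective sample size and mixing flags.
#
# The ESS estimator is the initial-positive-sequence truncated
# autocovariance sum: with empirical autocovariances
#   gamma(k) = (1/n) * sum_i (x_i - xbar)(x_{i+k} - xbar),
# accumulate V = gamma(0) and, for even k >= 2, add
# 2 * (gamma(k-1) + gamma(k)) while that pairwise sum stays positive,
# stopping at the first non-positive pair. Then
#   ACT = step_size * V / gamma(0)      (in state units)
#   ESS = n * step_size / ACT           (capped at n)
#   SE(mean) = sqrt(V / n).

DEFAULT_MAX_LAG <- 2000L

#' Autocorrelation time of an MCMC trace
#'
#' Estimates the autocorrelation time (ACT, in state units) and the
#' autocorrelation-corrected standard error of the mean by the paired
#' initial-positive-sequence truncation of the autocovariance sum.
#' Zero-variance chains are flagged degenerate and report
#' `act = step_size` by convention.
#'
#' @param values Numeric sample sequence (n >= 4).
#' @param step_size States between successive samples (default 1).
#' @param max_lag Truncation cap on the autocovariance lag
#'   (default 2000).
#' @return List with `act`, `stderr_of_mean`, `degenerate`, `var_sum`
#'   (the truncated sum V), `gamma0` and `n`.
#' @export
autocorrelation_time <- function(values, step_size = 1,
                                 max_lag = DEFAULT_MAX_LAG) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) {
    stop("need at least 4 samples to estimate autocorrelation time",
         call. = FALSE)
  }
  stopifnot(step_size > 0)
  x <- values - mean(values)
  gamma0 <- sum(x * x) / n
  if (gamma0 == 0) {
    return(list(act = step_size, stderr_of_mean = 0, degenerate = TRUE,
                var_sum = 0, gamma0 = 0, n = n))
  }
  gam <- function(k) sum(x[seq_len(n - k)] * x[(k + 1):n]) / n
  lag_cap <- min(n - 1L, max_lag)
  v <- gamma0
  k <- 2L
  while (k <= lag_cap) {
    pair <- gam(k - 1L) + gam(k)
    if (pair <= 0) break
    v <- v + 2 * pair
    k <- k + 2L
  }
  list(act = step_size * v / gamma0,
       stderr_of_mean = sqrt(v / n),
       degenerate = FALSE,
       var_sum = v, gamma0 = gamma0, n = n)
}

#' Effective sample size of an MCMC trace
#'
#' ESS = n * step_size / ACT, capped at n. A degenerate (zero-variance)
#' chain reports ESS = n so that fixed indicator columns do not produce
#' `NaN`.
#'
#' @inheritParams autocorrelation_time
#' @return Effective sample size (real, in `[0, n]`).
#' @export
ess <- function(values, step_size = 1, max_lag = DEFAULT_MAX_LAG) {
  a <- autocorrelation_time(values, step_size, max_lag)
  if (a$degenerate) return(a$n)
  min(a$n, a$n * step_size / a$act)
}

#' Classify an ESS against the conventional mixing cut-offs
#'
#' Uses the conventional cut-off values of 100 and 200: below 100 the
#' trace is flagged `LOW`, from 100 up to (but excluding) 200 `MEDIUM`,
#' and 200 or above `OK`.
#'
#' @param ess Effective sample size (non-negative).
#' @return `"LOW"`, `"MEDIUM"` or `"OK"`.
#' @export
classify_ess <- function(ess) {
  if (is.na(ess) || ess < 0) {
    stop("ESS must be a non-negative number", call. = FALSE)
  }
  if (ess < 100) "LOW" else if (ess < 200) "MEDIUM" else "OK"
}

#' Full mixing diagnostic for one trace
#'
#' Bundles ACT, ESS, the corrected standard error of the mean and the
#' LOW/MEDIUM/OK flag. Categorical traces have no meaningful ESS and
#' are rejected. For a combined trace (see [combine_traces()]) the ACT
#' is estimated within each component chain using its own sampling
#' interval, component ESS values are summed, and the reported ACT is
#' the pooled total of states divided by the pooled ESS.
#'
#' @param trace A `tk_trace` (from [get_trace()]) or numeric vector.
#' @param step_size Sampling interval; ignored when `trace` carries
#'   per-component intervals.
#' @param max_lag Truncation cap per component.
#' @return List with `act`, `ess`, `stderr_of_mean`, `flag`,
#'   `degenerate`, `n`.
#' @export
ess_diagnostic <- function(trace, step_size = 1,
                           max_lag = DEFAULT_MAX_LAG) {
  if (inherits(trace, "tk_trace")) {
    if (trace$type == "categorical") {
      stop(sprintf(
        "trace '%s' is categorical and has no ESS; use frequency_table()",
        trace$name), call. = FALSE)
    }
    if (!is.null(trace$components)) {
      parts <- lapply(trace$components, function(cmp)
        ess_diagnostic(cmp$values, cmp$step_size, max_lag))
      total_ess <- sum(vapply(parts, `[[`, numeric(1), "ess"))
      total_states <- sum(vapply(trace$components, function(cmp)
        length(cmp$values) * cmp$step_size, numeric(1)))
      se <- sqrt(sum(vapply(parts, function(p)
        p$stderr_of_mean^2 * p$n^2, numeric(1)))) / trace$n
      return(list(act = total_states / total_ess, ess = total_ess,
                  stderr_of_mean = se,
                  flag = classify_ess(total_ess),
                  degenerate = all(vapply(parts, `[[`, logical(1),
                                          "degenerate")),
                  n = trace$n))
    }
    values <- trace$values
  } else {
    values <- as.numeric(trace)
  }
  a <- autocorrelation_time(values, step_size, max_lag)
  e <- if (a$degenerate) a$n else min(a$n, a$n * step_size / a$act)
  list(act = a$act, ess = e, stderr_of_mean = a$stderr_of_mean,
       flag = classify_ess(e), degenerate = a$degenerate, n = a$n)
}
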