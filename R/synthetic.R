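# Seedable synthetic trace generators.
#
# Every generator is a pure function of its seed and parameters:
# randomness runs through withr::with_seed, so the caller's global RNG
# state is never consumed or disturbed. Chain specs derive one
# deterministic sub-seed per column from the spec seed.

column_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 77003 * i) %% 2147483587)
}

#' Generate a stationary AR(1) chain
#'
#' First-order autoregressive sequence with the given marginal mean and
#' standard deviation: `x_t = phi x_{t-1} + e_t` with innovation
#' variance `sd^2 (1 - phi^2)` and a stationary start. The closed-form
#' integrated autocorrelation time of this process,
#' `(1 + phi) / (1 - phi)` sampling intervals, makes it the standard
#' calibration target for ESS estimators.
#'
#' @param n Number of samples (>= 2).
#' @param phi Autoregressive coefficient, |phi| < 1.
#' @param mean,sd Marginal mean and standard deviation.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return Numeric vector of length `n`.
#' @export
gen_ar1 <- function(n, phi, mean = 0, sd = 1, seed = 1) {
  stopifnot(n >= 2, sd > 0)
  if (abs(phi) >= 1) {
    stop("AR(1) coefficient must satisfy |phi| < 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
    e[1] <- stats::rnorm(1, 0, sd)  # stationary start
    mean + as.numeric(stats::filter(e, phi, method = "recursive"))
  })
}

#' Generate i.i.d. normal samples
#'
#' @inheritParams gen_ar1
#' @return Numeric vector of length `n`.
#' @export
gen_iid_normal <- function(n, mean = 0, sd = 1, seed = 1) {
  stopifnot(n >= 1, sd > 0)
  withr::with_seed(seed, stats::rnorm(n, mean, sd))
}

#' Generate a BSSVS indicator/rate pair
#'
#' Emulates Bayesian stochastic search variable selection output: a
#' binary indicator drawn Bernoulli(`p_on`) and a rate drawn from the
#' "on" distribution (log-normal with mean `rate_on_mean` and
#' coefficient of variation ~0.25) when the indicator is 1, and from a
#' near-zero slab (mean `rate_on_mean / 1000`) otherwise.
#'
#' @param n Number of samples.
#' @param p_on Prior-like inclusion probability in (0, 1).
#' @param rate_on_mean Mean of the "on" rate distribution.
#' @param seed Integer seed.
#' @return List with `indicator` (0/1 integers) and `rate` (positive
#'   reals).
#' @export
gen_bssvs_pair <- function(n, p_on, rate_on_mean = 1, seed = 1) {
  stopifnot(n >= 1, p_on > 0, p_on < 1, rate_on_mean > 0)
  sigma <- 0.25
  withr::with_seed(seed, {
    ind <- stats::rbinom(n, 1L, p_on)
    on <- stats::rlnorm(n, log(rate_on_mean) - sigma^2 / 2, sigma)
    slab <- stats::rlnorm(n, log(rate_on_mean / 1000) - sigma^2 / 2, sigma)
    list(indicator = ind, rate = ifelse(ind == 1, on, slab))
  })
}

#' Generate categorical samples
#'
#' @param n Number of samples.
#' @param levels Character vector of level labels.
#' @param probs Level probabilities (summing to 1).
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
gen_categorical <- function(n, levels, probs = NULL, seed = 1) {
  if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
  stopifnot(length(levels) == length(probs),
            abs(sum(probs) - 1) < 1e-9)
  withr::with_seed(seed,
    sample(as.character(levels), n, replace = TRUE, prob = probs))
}

# ---- column generator descriptors ------------------------------------

#' Column generators for synthetic chain specs
#'
#' Descriptors consumed by [chain_spec()]: an AR(1) column, an i.i.d.
#' normal column, a linked BSSVS indicator/rate column pair, a block of
#' skygrid log-population-size columns, or a categorical column.
#'
#' @param name,rate_name,prefix Column name(s) to emit.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param mean,sd Marginal mean and standard deviation.
#' @param p_on Inclusion probability in (0, 1).
#' @param rate_on_mean Mean of the "on" rate distribution.
#' @param K Number of skygrid bins; columns are named
#'   `<prefix>1..<prefix>K`.
#' @param log_means Length-K vector of per-bin mean log population
#'   sizes.
#' @param noise_sd Standard deviation of per-sample noise around
#'   `log_means` (0 gives a deterministic step function).
#' @param levels,probs Categorical levels and probabilities.
#' @return A column-generator descriptor.
#' @name chain_columns
NULL

#' @rdname chain_columns
#' @export
col_ar1 <- function(name, phi, mean = 0, sd = 1) {
  stopifnot(abs(phi) < 1)
  structure(list(kind = "ar1", name = name, phi = phi,
                 mean = mean, sd = sd), class = "tk_column")
}

#' @rdname chain_columns
#' @export
col_iid_normal <- function(name, mean = 0, sd = 1) {
  structure(list(kind = "iid_normal", name = name, mean = mean, sd = sd),
            class = "tk_column")
}

#' @rdname chain_columns
#' @export
col_indicator <- function(name, p_on, rate_name = NULL,
                          rate_on_mean = 1) {
  stopifnot(p_on > 0, p_on < 1)
  structure(list(kind = "indicator", name = name, p_on = p_on,
                 rate_name = rate_name, rate_on_mean = rate_on_mean),
            class = "tk_column")
}

#' @rdname chain_columns
#' @export
col_skygrid <- function(prefix, K, log_means, noise_sd = 0) {
  stopifnot(K >= 1, length(log_means) == K, noise_sd >= 0)
  structure(list(kind = "skygrid", name = prefix, K = K,
                 log_means = log_means, noise_sd = noise_sd),
            class = "tk_column")
}

#' @rdname chain_columns
#' @export
col_categorical <- function(name, levels, probs = NULL) {
  if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
  stopifnot(length(levels) == length(probs),
            abs(sum(probs) - 1) < 1e-9)
  structure(list(kind = "categorical", name = name,
                 levels = as.character(levels), probs = probs),
            class = "tk_column")
}

#' Specify a synthetic MCMC chain
#'
#' Bundles a sample count, sampling interval, seed and a list of column
#' generators (see [chain_columns]) into a reproducible recipe for a
#' synthetic trace file.
#'
#' @param n Number of samples (>= 2).
#' @param step_size States between samples (positive integer).
#' @param seed Integer master seed; per-column sub-seeds are derived
#'   deterministically from it.
#' @param columns List of column generators.
#' @return A `chain_spec`.
#' @export
chain_spec <- function(n, step_size = 1, seed = 1, columns) {
  stopifnot(n >= 2, step_size >= 1, length(columns) >= 1,
            all(vapply(columns, inherits, logical(1), "tk_column")))
  structure(list(n = as.integer(n), step_size = as.integer(step_size),
                 seed = as.integer(seed), columns = columns),
            class = "chain_spec")
}

#' Generate the data of a chain spec
#'
#' Materializes every column of a [chain_spec()] deterministically from
#' the spec seed.
#'
#' @param spec A `chain_spec`.
#' @return List with `states`, `values` (named list of columns) and
#'   `types` (named character vector).
#' @export
generate_chain <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  values <- list()
  types <- character(0)
  for (i in seq_along(spec$columns)) {
    cl <- spec$columns[[i]]
    s <- column_seed(spec$seed, i)
    if (cl$kind == "ar1") {
      values[[cl$name]] <- gen_ar1(spec$n, cl$phi, cl$mean, cl$sd, s)
      types[cl$name] <- "real"
    } else if (cl$kind == "iid_normal") {
      values[[cl$name]] <- gen_iid_normal(spec$n, cl$mean, cl$sd, s)
      types[cl$name] <- "real"
    } else if (cl$kind == "indicator") {
      pair <- gen_bssvs_pair(spec$n, cl$p_on, cl$rate_on_mean, s)
      values[[cl$name]] <- pair$indicator
      types[cl$name] <- "integer"
      if (!is.null(cl$rate_name)) {
        values[[cl$rate_name]] <- pair$rate
        types[cl$rate_name] <- "real"
      }
    } else if (cl$kind == "skygrid") {
      theta <- withr::with_seed(s, {
        matrix(stats::rnorm(spec$n * cl$K,
                            mean = rep(cl$log_means, each = spec$n),
                            sd = cl$noise_sd),
               nrow = spec$n, ncol = cl$K)
      })
      for (j in seq_len(cl$K)) {
        nm <- paste0(cl$name, j)
        values[[nm]] <- theta[, j]
        types[nm] <- "real"
      }
    } else if (cl$kind == "categorical") {
      values[[cl$name]] <- gen_categorical(spec$n, cl$levels, cl$probs, s)
      types[cl$name] <- "categorical"
    }
  }
  list(states = as.numeric(seq(0L, by = spec$step_size,
                               length.out = spec$n)),
       values = values, types = types)
}

#' Write a synthetic chain spec as a dialect-correct log file
#'
#' Emits a log file that [parse_log()] reads back with identical values
#' (numbers are printed at full double precision) and whose dialect is
#' auto-detected.
#'
#' @param spec A `chain_spec`.
#' @param path Output path.
#' @param dialect `"beast"` or `"mrbayes"`.
#' @return `path`, invisibly.
#' @export
write_log <- function(spec, path, dialect = c("beast", "mrbayes")) {
  dialect <- match.arg(dialect)
  dat <- generate_chain(spec)
  nm <- names(dat$values)
  body <- vapply(seq_along(dat$states), function(i) {
    row <- vapply(nm, function(cn)
      format_log_value(dat$values[[cn]][i], dat$types[[cn]]),
      character(1))
    paste(c(sprintf("%d", as.integer(dat$states[i])), row),
          collapse = "\t")
  }, character(1))
  if (dialect == "beast") {
    lines <- c(sprintf("# synthetic trace (seed %d)", spec$seed),
               sprintf("# %d samples every %d states", spec$n,
                       spec$step_size),
               paste(c("state", nm), collapse = "\t"), body)
  } else {
    lines <- c(sprintf("[ID: %07d]", spec$seed),
               paste(c("Gen", nm), collapse = "\t"), body)
  }
  writeLines(lines, path)
  invisible(path)
}
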