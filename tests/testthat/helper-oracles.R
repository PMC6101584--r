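# Independent oracles: literal, loop-based transcriptions of the
# estimator definitions, kept deliberately naive so they share no code
# with the implementations they check.

# Truncated autocovariance sum with paired initial-positive-sequence
# stopping, written as explicit double loops.
act_oracle <- function(x, step_size = 1, max_lag = 2000) {
  n <- length(x)
  xbar <- mean(x)
  gam <- function(k) {
    s <- 0
    for (i in 1:(n - k)) s <- s + (x[i] - xbar) * (x[i + k] - xbar)
    s / n
  }
  g0 <- gam(0)
  if (g0 == 0) return(list(act = step_size, stderr = 0, degenerate = TRUE))
  lag_cap <- min(n - 1, max_lag)
  v <- g0
  k <- 2
  while (k <= lag_cap) {
    pair <- gam(k - 1) + gam(k)
    if (pair <= 0) break
    v <- v + 2 * pair
    k <- k + 2
  }
  list(act = step_size * v / g0, stderr = sqrt(v / n), degenerate = FALSE)
}

# Exhaustive enumeration of every contiguous sorted window.
hpd_oracle <- function(values, proportion = 0.95) {
  s <- sort(values)
  n <- length(s)
  m <- max(1, floor(proportion * n + 0.5))
  best_i <- 1
  best_w <- Inf
  for (i in 1:(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best_w) {  # strict: ties keep the lowest start index
      best_w <- w
      best_i <- i
    }
  }
  c(s[best_i], s[best_i + m - 1])
}

# Write a minimal BEAST-dialect log from explicit columns and parse it
# back with zero burn-in: a convenient way to build trace_file objects
# with known contents in tests.
make_trace_file <- function(columns, step_size = 1, states = NULL,
                            burnin = 0, path = tempfile(fileext = ".log")) {
  n <- length(columns[[1]])
  if (is.null(states)) states <- seq(0, by = step_size, length.out = n)
  fmt <- function(v) {
    if (is.character(v)) v else sprintf("%.17g", v)
  }
  rows <- vapply(seq_len(n), function(i) {
    paste(c(sprintf("%d", as.integer(states[i])),
            vapply(columns, function(cl) fmt(cl[i])[1], character(1))),
          collapse = "\t")
  }, character(1))
  writeLines(c("# test fixture",
               paste(c("state", names(columns)), collapse = "\t"),
               rows), path)
  parse_log(path, burnin = burnin)
}

random_chain_spec <- function(seed) {
  withr::with_seed(seed, {
    cols <- list(
      col_ar1("posterior", phi = stats::runif(1, -0.5, 0.9),
              mean = stats::rnorm(1, 0, 10), sd = stats::runif(1, 0.5, 3)),
      col_iid_normal("kappa", mean = stats::runif(1, 1, 5),
                     sd = stats::runif(1, 0.1, 1)),
      col_indicator("indicator", p_on = stats::runif(1, 0.2, 0.8),
                    rate_name = "rate",
                    rate_on_mean = stats::runif(1, 0.5, 2)),
      col_categorical("host", levels = c("hostA", "hostB", "hostC"),
                      probs = c(0.5, 0.3, 0.2)))
    chain_spec(n = sample(20:80, 1), step_size = sample(c(1, 10, 500), 1),
               seed = seed, columns = cols)
  })
}
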