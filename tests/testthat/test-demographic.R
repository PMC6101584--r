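test_that("parametric population-size functions evaluate correctly", {
  exp_m <- demographic_model("exponential", columns = c(N0 = "n0", r = "r"))
  expect_equal(pop_size_at(exp_m, list(N0 = 1, r = 1), 1), exp(-1))
  expect_equal(pop_size_at(exp_m, list(N0 = 3, r = 0), c(0, 5, 50)),
               rep(3, 3))

  con_m <- demographic_model("constant", columns = c(N0 = "n0"))
  expect_equal(pop_size_at(con_m, list(N0 = 7), c(0, 1, 2)), rep(7, 3))

  log_m <- demographic_model("logistic",
                             columns = c(N0 = "n0", r = "r", c = "c"))
  expect_equal(pop_size_at(log_m, list(N0 = 2, r = 0.5, c = 1), 0), 2)
  # far in the past a growing logistic population shrinks toward zero
  expect_lt(pop_size_at(log_m, list(N0 = 2, r = 0.5, c = 1), 50), 1e-9)

  expect_error(pop_size_at(exp_m, list(N0 = -1, r = 1), 1), "N0")
  expect_error(pop_size_at(log_m, list(N0 = 1, r = 1, c = -2), 1), "c")
})

test_that("skygrid lookup is piecewise constant with the last bin extended", {
  m <- demographic_model("skygrid", theta_columns = c("t1", "t2"),
                         cutoff = 10)
  th <- list(theta = c(log(2), log(8)))
  expect_equal(pop_size_at(m, th, 3), 2)
  expect_equal(pop_size_at(m, th, 7), 8)
  expect_equal(pop_size_at(m, th, 12), 8)
  expect_equal(pop_size_at(m, th, c(0, 4.999, 5)), c(2, 2, 8))
})

test_that("model construction validates its column map", {
  expect_error(demographic_model("exponential", columns = c(N0 = "n0")),
               "r")
  expect_error(demographic_model("skygrid", theta_columns = "t1"),
               "cutoff")
})

test_that("skygrid columns are discovered and ordered by trailing index", {
  tf <- make_trace_file(list(
    "pop.theta10" = c(1, 2, 3), "pop.theta2" = c(1, 2, 3),
    "pop.theta1" = c(1, 2, 3), other = c(1, 2, 3)))
  expect_identical(skygrid_columns(tf, "pop.theta"),
                   c("pop.theta1", "pop.theta2", "pop.theta10"))
  expect_error(skygrid_columns(tf, "nope"), "no columns")
})

test_that("constant-model reconstruction gives a flat pointwise median", {
  tf <- make_trace_file(list(N0 = rep(c(1, 2, 3), 4)))
  m <- demographic_model("constant", columns = c(N0 = "N0"))
  ts <- reconstruct_trajectory(tf, m, grid_points = 7, t_max = 6)
  expect_equal(ts$median, rep(2, 7))
  expect_equal(ts$times, seq(0, 6, length.out = 7))
})

test_that("per-time HPD equals hpd_interval on the per-sample matrix column", {
  tf <- make_trace_file(list(
    N0 = exp(gen_iid_normal(40, mean = log(10), sd = 0.3, seed = 5)),
    r = gen_iid_normal(40, mean = 0.5, sd = 0.1, seed = 6)))
  m <- demographic_model("exponential", columns = c(N0 = "N0", r = "r"))
  ts <- reconstruct_trajectory(tf, m, grid_points = 9, t_max = 4,
                               keep_samples = TRUE)
  for (j in seq_along(ts$times)) {
    ref <- hpd_interval(ts$per_sample_matrix[, j], 0.95)
    expect_equal(c(ts$hpd_lower[j], ts$hpd_upper[j]), ref)
    expect_equal(ts$median[j],
                 stats::median(ts$per_sample_matrix[, j]))
  }
})

test_that("zero-noise skygrid reconstruction recovers the exact step function", {
  spec <- chain_spec(n = 50, step_size = 1, seed = 3, columns = list(
    col_skygrid("theta", K = 2, log_means = c(log(2), log(8)),
                noise_sd = 0)))
  p <- tempfile()
  write_log(spec, p)
  tf <- parse_log(p, burnin = 0)
  m <- demographic_model("skygrid",
                         theta_columns = skygrid_columns(tf, "theta"),
                         cutoff = 10)
  ts <- reconstruct_trajectory(tf, m, grid_points = 21)
  expect_equal(ts$median[ts$times < 5], rep(2, sum(ts$times < 5)))
  expect_equal(ts$median[ts$times >= 5], rep(8, sum(ts$times >= 5)))
  expect_equal(ts$hpd_lower, ts$median)
  expect_equal(ts$hpd_upper, ts$median)
})

test_that("exponential-growth posteriors recover the simulated trajectory", {
  at0 <- numeric(10); at2 <- numeric(10)
  for (s in 1:10) {
    tf <- make_trace_file(list(
      N0 = exp(gen_iid_normal(200, mean = log(10), sd = 0.05,
                              seed = 700 + s)),
      r = rep(0.5, 200)))
    m <- demographic_model("exponential", columns = c(N0 = "N0", r = "r"))
    ts <- reconstruct_trajectory(tf, m, grid_points = 5, t_max = 2)
    at0[s] <- ts$median[1]
    at2[s] <- ts$median[5]
  }
  expect_lt(abs(mean(at0) - 10) / 10, 0.10)
  expect_lt(abs(mean(at2) - 10 * exp(-1)) / (10 * exp(-1)), 0.15)
})

test_that("log-scale and natural-scale medians commute with exponentiation", {
  spec <- chain_spec(n = 61, step_size = 1, seed = 12, columns = list(
    col_skygrid("theta", K = 3, log_means = c(0, 1, 2), noise_sd = 0.4)))
  p <- tempfile()
  write_log(spec, p)
  tf <- parse_log(p, burnin = 0)
  m <- demographic_model("skygrid",
                         theta_columns = skygrid_columns(tf, "theta"),
                         cutoff = 9)
  nat <- reconstruct_trajectory(tf, m, grid_points = 10)
  lg <- reconstruct_trajectory(tf, m, grid_points = 10, scale = "log")
  expect_equal(lg$median, nat$median, tolerance = 1e-12)
})

test_that("reconstruction validates its inputs", {
  tf <- make_trace_file(list(N0 = rep(c(1, 2, 3), 4)))
  m <- demographic_model("constant", columns = c(N0 = "missingCol"))
  expect_error(reconstruct_trajectory(tf, m, t_max = 1), "missingCol")

  small <- make_trace_file(list(N0 = c(1, 2, 3)))
  m2 <- demographic_model("constant", columns = c(N0 = "N0"))
  expect_error(reconstruct_trajectory(small, m2, t_max = 1),
               "at least 10")
})
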