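discrete_trace <- function(values, name = "g") {
  tf <- make_trace_file(stats::setNames(list(values), name))
  get_trace(tf, name)
}

test_that("joint probability tables count level pairs", {
  jt <- joint_probability(c(0, 0, 1, 1), c("x", "x", "y", "y"))
  expect_equal(jt$joint_prob["0", "x"], 0.5)
  expect_equal(jt$joint_prob["1", "y"], 0.5)
  expect_equal(jt$joint_prob["0", "y"], 0)
  expect_equal(sum(jt$joint_prob), 1, tolerance = 1e-12)
})

test_that("joint-table marginals reproduce each trace's frequency table", {
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(10:200, 1)
      a <- sample(0:3, n, replace = TRUE)
      b <- sample(letters[1:4], n, replace = TRUE)
      jt <- joint_probability(a, b)
      fa <- frequency_table(a, type = "integer")
      fb <- frequency_table(b, type = "categorical")
      expect_equal(unname(rowSums(jt$joint_prob)), fa$probabilities,
                   tolerance = 1e-12)
      expect_equal(unname(colSums(jt$joint_prob)), fb$probabilities,
                   tolerance = 1e-12)
      expect_equal(sum(jt$joint_prob), 1, tolerance = 1e-12)
    }
  })
})

test_that("independent discrete traces have near-product joint probabilities", {
  withr::with_seed(21, {
    a <- sample(0:4, 100000, replace = TRUE)
    b <- sample(0:4, 100000, replace = TRUE)
  })
  jt <- joint_probability(a, b)
  marg <- outer(rowSums(jt$joint_prob), colSums(jt$joint_prob))
  expect_lt(max(abs(jt$joint_prob - marg)), 0.01)
})

test_that("joint tables reject misaligned or continuous input", {
  expect_error(joint_probability(c(0, 1), c(0, 1, 0)), "not aligned")
  expect_error(joint_probability(c(0.5, 1.5, 2.5), c(0, 1, 0)),
               "discrete")
})

test_that("correlation matrices carry the standard ellipse glyph parameters", {
  cm <- pearson_matrix(list(x = c(1, 2, 3), y = c(2, 4, 6)))
  expect_equal(cm$r[1, 2], 1)
  expect_equal(cm$ellipses[[1]]$semi_minor, 0)   # perfect correlation: a line
  expect_equal(cm$ellipses[[1]]$orientation, 45)

  cm <- pearson_matrix(list(x = c(1, 2, 3), y = c(6, 4, 2)))
  expect_equal(cm$r[1, 2], -1)
  expect_equal(cm$ellipses[[1]]$orientation, -45)

  e <- tracekit:::ellipse_params(0)               # no correlation: a circle
  expect_equal(e$semi_major, 1)
  expect_equal(e$semi_minor, 1)
})

test_that("Pearson matrix is invariant under positive affine maps and flips under negative", {
  x <- gen_iid_normal(200, seed = 31)
  y <- x + gen_iid_normal(200, seed = 32)
  r0 <- pearson_matrix(list(x = x, y = y))$r[1, 2]
  r_aff <- pearson_matrix(list(x = 3.2 * x + 7, y = y))$r[1, 2]
  r_neg <- pearson_matrix(list(x = -2 * x + 1, y = y))$r[1, 2]
  expect_equal(r_aff, r0, tolerance = 1e-9)
  expect_equal(r_neg, -r0, tolerance = 1e-9)
})

test_that("degenerate traces are rejected by name", {
  expect_error(pearson_matrix(list(flat = c(2, 2, 2), y = c(1, 2, 3))),
               "flat")
})

test_that("scatter data passes aligned pairs through with r attached", {
  x <- gen_iid_normal(50, seed = 41)
  y <- gen_iid_normal(50, seed = 42)
  sd_ <- scatter_data(x, y)
  expect_identical(nrow(sd_), 50L)
  expect_equal(attr(sd_, "r"), pearson_matrix(list(a = x, b = y))$r[1, 2])
  expect_equal(attr(scatter_data(x, x), "r"), 1)
})

test_that("conditional summaries restrict to each level's samples", {
  cs <- conditional_summary(c(0.1, 0.2, 5, 6), c(0, 0, 1, 1))
  expect_equal(cs$per_level[["1"]]$summary$mean, 5.5)
  expect_equal(cs$per_level[["0"]]$summary$mean, 0.15)
  expect_identical(sum(cs$per_level_n), 4L)
})

test_that("conditional summaries equal a filter-then-summarize oracle", {
  withr::with_seed(53, {
    for (i in 1:10) {
      n <- sample(30:150, 1)
      x <- rnorm(n)
      g <- sample(0:2, n, replace = TRUE)
      cs <- conditional_summary(x, g)
      for (lev in cs$levels) {
        sub <- x[g == lev]
        if (length(sub) >= 2) {
          ref <- summarize_trace(sub)
          got <- cs$per_level[[as.character(lev)]]$summary
          expect_equal(got$mean, ref$mean)
          expect_equal(got$median, ref$median)
          expect_equal(c(got$hpd_lower, got$hpd_upper),
                       c(ref$hpd_lower, ref$hpd_upper))
        }
      }
    }
  })
})

test_that("single-level conditioning reproduces the unconditional summary", {
  x <- gen_iid_normal(100, seed = 61)
  cs <- conditional_summary(x, rep(1L, 100))
  s <- summarize_trace(x)
  got <- cs$per_level[["1"]]$summary
  expect_equal(got$mean, s$mean)
  expect_equal(got$stdev, s$stdev)
  expect_equal(c(got$hpd_lower, got$hpd_upper),
               c(s$hpd_lower, s$hpd_upper))
})

test_that("levels observed once report counts only and are flagged", {
  cs <- conditional_summary(c(1, 2, 3, 9), c(0, 0, 0, 5))
  expect_true(cs$per_level[["5"]]$summary$insufficient)
  expect_identical(cs$per_level[["5"]]$summary$n, 1L)
})

test_that("BSSVS rate summaries condition on indicator = 1", {
  s <- bssvs_rate_summary(c(0.1, 0.2, 5, 6), c(0L, 0L, 1L, 1L))
  expect_equal(s$mean, 5.5)
  expect_equal(s$inclusion_prob, 0.5)

  x <- gen_iid_normal(100, seed = 71, mean = 2)
  all_on <- bssvs_rate_summary(x, rep(1L, 100))
  ref <- summarize_trace(x)
  expect_equal(all_on$mean, ref$mean)
  expect_equal(all_on$inclusion_prob, 1)

  expect_error(bssvs_rate_summary(c(1, 2, 3), c(0L, 0L, 0L)),
               "no support")
  expect_error(bssvs_rate_summary(c(1, 2, 3), c(0L, 1L, 2L)),
               "binary")
})

test_that("BSSVS conditioning agrees with conditional_summary at level 1", {
  pair <- gen_bssvs_pair(2000, 0.6, 1.5, seed = 81)
  s <- bssvs_rate_summary(pair$rate, pair$indicator)
  cs <- conditional_summary(pair$rate, pair$indicator)
  ref <- cs$per_level[["1"]]$summary
  expect_equal(s$mean, ref$mean)
  expect_equal(s$median, ref$median)
  expect_equal(c(s$hpd_lower, s$hpd_upper),
               c(ref$hpd_lower, ref$hpd_upper))
})
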