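test_that("internal standard location picks the most intense in-window peak", {
  peaks <- data.frame(mz = c(1157.30, 1257.42), intensity = c(500, 900),
                      mode = "positive")
  expect_equal(locate_internal_standard(peaks, "positive")$mz, 1157.30)
  peaks2 <- data.frame(mz = c(1157.20, 1157.31), intensity = c(100, 400),
                       mode = "positive")
  expect_equal(locate_internal_standard(peaks2, "positive")$mz, 1157.31)
  peaks3 <- data.frame(mz = 1257.42, intensity = 900, mode = "positive")
  expect_error(locate_internal_standard(peaks3, "positive"),
               "missing internal standard")
})

test_that("normalization scales to 100 x ratio and preserves zeros", {
  peaks <- data.frame(mz = c(1157.25, 1300, 1400),
                      intensity = c(900, 450, 0), mode = "positive")
  is_peak <- locate_internal_standard(peaks, "positive")
  corr <- normalize_intensities(peaks, is_peak)
  expect_equal(corr$intensity, c(100, 50, 0))
  bad <- data.frame(mz = 1157.25, intensity = 0, mode = "positive")
  expect_error(normalize_intensities(peaks, bad), "must be > 0")
})

test_that("normalization is invariant to rescaling all raw intensities", {
  set.seed(1)
  peaks <- data.frame(mz = c(1157.25, runif(10, 900, 2000)),
                      intensity = c(800, runif(10, 1, 1000)),
                      mode = "positive")
  for (k in c(0.01, 3, 1e4)) {
    scaled <- peaks
    scaled$intensity <- scaled$intensity * k
    expect_equal(normalize_peaklist(scaled)$intensity,
                 normalize_peaklist(peaks)$intensity, tolerance = 1e-12)
  }
})

test_that("group aggregation includes zeros and calls detectability", {
  am <- make_matrix(list(
    "(Hex)6 [M+Na]+" = c(22.95, 0, 0, 0, 0, 0, 5, 5, 5),
    "(Hex)7 [M+Na]+" = c(1, 2, 3, 4, 5, 6, 7, 8, 9)))
  # single nonzero replicate: the published "7.65 +/- 13.24"-style cell
  a <- aggregate_group(am, "(Hex)6 [M+Na]+", "control")
  expect_equal(a$mean, 7.65)
  expect_equal(a$sd, 13.2502, tolerance = 1e-4)
  expect_true(a$detectable)
  # all-zero group is undetectable with mean = sd = 0
  b <- aggregate_group(am, "(Hex)6 [M+Na]+", "model")
  expect_false(b$detectable)
  expect_equal(b$mean, 0)
  expect_equal(b$sd, 0)
  # constant replicates
  c3 <- aggregate_group(am, "(Hex)6 [M+Na]+", "treated")
  expect_equal(c3$mean, 5)
  expect_equal(c3$sd, 0)
  expect_error(aggregate_group(am, "nope", "control"), "unknown species")
  expect_error(aggregate_group(am, "(Hex)6 [M+Na]+", "placebo"),
               "unknown group")
})

test_that("n x mean equals the replicate sum exactly", {
  set.seed(8)
  vals <- matrix(stats::rexp(9 * 4, 1 / 30), nrow = 9)
  colnames(vals) <- sprintf("(Hex)%d [M+Na]+", 3:6)
  am <- make_matrix(as.list(as.data.frame(vals)))
  sm <- summarize_groups(am)
  for (i in seq_len(nrow(sm))) {
    ids <- am$samples$sample_id[am$samples$group == sm$group[i]]
    expect_equal(sm$n[i] * sm$mean[i], sum(am$values[ids, sm$species[i]]),
                 tolerance = 1e-12)
  }
})

test_that("Dixon's Q-test matches the published critical table", {
  r <- dixon_outlier_test(c(1.0, 1.1, 5.0), alpha = 0.05)
  expect_equal(r$Q, 0.975)
  expect_equal(r$critical, 0.970)
  expect_true(r$flagged)
  expect_equal(r$suspect, 3L)
  r2 <- dixon_outlier_test(c(1, 2, 3), alpha = 0.05)
  expect_equal(r2$Q, 0.5)
  expect_false(r2$flagged)
  r3 <- dixon_outlier_test(c(4, 4, 4))
  expect_false(r3$flagged)
  expect_match(r3$note, "zero range")
  expect_error(dixon_outlier_test(c(1, 2)), "insufficient data")
  expect_error(dixon_outlier_test(1:11), "n <= 10")
  # stricter level needs a larger Q
  expect_false(dixon_outlier_test(c(1.0, 1.1, 5.0), alpha = 0.01)$flagged)
})

test_that("Dixon flag is invariant under affine transforms", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    x <- stats::rnorm(n)
    base <- dixon_outlier_test(x)
    for (ab in list(c(3, 2), c(-1.5, 10), c(0.02, -4))) {
      y <- ab[1] * x + ab[2]
      r <- dixon_outlier_test(y)
      expect_equal(r$Q, base$Q, tolerance = 1e-9)
      expect_identical(r$flagged, base$flagged)
    }
  }
})

test_that("matrix-wide outlier screen reports per-cell results", {
  am <- make_matrix(list(
    "(Hex)6 [M+Na]+" = c(1.0, 1.1, 5.0, 2, 2, 2, 1, 2, 3)))
  sc <- screen_outliers(am)
  expect_equal(nrow(sc), 3L)
  expect_true(sc$flagged[sc$group == "control"])
  expect_false(sc$flagged[sc$group == "treated"])
})
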