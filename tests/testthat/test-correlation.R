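test_that("discrimination index is the novel-object time share", {
  expect_equal(discrimination_index(30, 30), 50)
  expect_equal(discrimination_index(45, 15), 75)
  expect_equal(discrimination_index(0, 20), 0)
  expect_error(discrimination_index(0, 0), "zero total exploration")
  expect_error(discrimination_index(-1, 5), "non-negative")
})

test_that("Pearson correlation matches the closed forms and cor.test", {
  # hand-verifiable small case
  r <- pearson_correlation(1:5, c(2, 1, 4, 3, 6))
  expect_equal(r$r, 0.82199, tolerance = 1e-4)
  expect_equal(r$p, 0.08771, tolerance = 1e-4)
  # independent oracle: cor.test for r, p and the Fisher interval
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n)
    y <- 0.5 * x + stats::rnorm(n)
    mine <- pearson_correlation(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    expect_equal(c(mine$ci_lower, mine$ci_upper),
                 as.numeric(ref$conf.int), tolerance = 1e-9)
    expect_true(mine$ci_lower <= mine$r && mine$r <= mine$ci_upper)
  }
  # perfect linear relations
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$p, 0)
  expect_error(pearson_correlation(1:2, 1:2), "insufficient data")
  expect_error(pearson_correlation(1:5, rep(2, 5)), "constant")
})

test_that("r is affine-invariant and the CI narrows with n", {
  set.seed(23)
  x <- stats::rnorm(30)
  y <- 0.7 * x + stats::rnorm(30, sd = 0.5)
  base <- pearson_correlation(x, y)
  shifted <- pearson_correlation(3 * x + 5, 0.2 * y - 1)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  flipped <- pearson_correlation(-x, y)
  expect_equal(flipped$r, -base$r, tolerance = 1e-12)
  # deterministic CI width comparison at fixed r
  width <- function(n) {
    ci <- tanh(atanh(0.6) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
    diff(ci)
  }
  widths <- vapply(c(5, 10, 20, 50, 100), width, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the glycan-behavior screen flags a planted correlation", {
  cfg <- correlation_calibration_config(r = 0.9, n_per_group = 10, seed = 77)
  coh <- generate_cohort(cfg)
  am <- quantify_cohort(coh, method = "targeted")
  res <- screen_glycan_behavior(am, coh$behavior,
                                species = cfg$planted$species,
                                measures = "di_short")
  expect_true(res$flagged)
  # observed r lies within the Fisher 95% bounds around the planted value
  n <- res$n
  bounds <- tanh(atanh(0.9) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
  expect_gt(res$r, bounds[1])
  expect_lt(res$r, bounds[2])
  # permuting subjects destroys the association
  set.seed(5)
  beh <- coh$behavior
  beh$subject_id <- sample(beh$subject_id)
  perm <- screen_glycan_behavior(am, beh, species = cfg$planted$species,
                                 measures = "di_short")
  expect_lt(abs(perm$r), abs(res$r))
  # too little overlap is an error
  expect_error(screen_glycan_behavior(am, coh$behavior[1:2, ]),
               "insufficient data|overlapping")
})
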