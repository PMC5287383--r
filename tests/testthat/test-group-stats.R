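test_that("pooled t from summaries reproduces the hand-computed cortex case", {
  # mean/SD cells of the strongly changed cortex species, n = 3 per group
  r <- students_t_from_summary(69.68, 7.52, 3, 33.75, 2.30, 3)
  expect_equal(r$statistic, 7.9137, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_lt(r$p_two_tailed, 0.01)
  expect_equal(r$p_two_tailed, 0.0013796, tolerance = 1e-4)
})

test_that("raw-replicate t agrees with the summary form and with t.test", {
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:8, 1), mean = 10, sd = 2)
    y <- stats::rnorm(sample(3:8, 1), mean = 12, sd = 3)
    mine <- students_t(x, y)
    from_summary <- students_t_from_summary(mean(x), sd(x), length(x),
                                            mean(y), sd(y), length(y))
    expect_equal(mine$statistic, from_summary$statistic, tolerance = 1e-9)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-9)
  }
  # identical groups: t = 0, p = 1
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_tailed, 1)
  expect_error(students_t(c(1, 1, 1), c(2, 2, 2)), "both SDs are zero")
  expect_error(students_t_from_summary(1, 1, 1, 2, 1, 3), "n >= 2")
})

test_that("one-way ANOVA matches the hand-computed decomposition", {
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$statistic, 3.0, tolerance = 1e-9)
  expect_equal(r$df, c(2, 6))
  # two groups: F = t^2
  set.seed(31)
  for (i in 1:10) {
    x <- stats::rnorm(4); y <- stats::rnorm(5, 1)
    expect_equal(one_way_anova(list(x, y))$statistic,
                 students_t(x, y)$statistic^2, tolerance = 1e-9)
  }
  expect_match(one_way_anova(list(c(2, 2), c(2, 2)))$note, "no test")
  expect_error(one_way_anova(list(1, c(1, 2))), "n >= 2")
})

test_that("modulation classification follows the detectability rules", {
  summaries <- data.frame(
    species = rep(c("a", "b", "c", "d"), each = 3),
    group = rep(group_levels(), times = 4),
    n = 3,
    mean = c(10, 0, 12,   0, 8, 0,   0, 0, 9,   5, 5, 5),
    sd = 1,
    detectable = c(TRUE, FALSE, TRUE,  FALSE, TRUE, FALSE,
                   FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  calls <- classify_modulation(summaries)
  row <- function(s) calls[calls$species == s, ]
  # detectable control only: control-only and (treated detectable) induced
  expect_true(row("a")$control_only)
  expect_true(row("a")$treatment_induced)
  # model-only and suppressed can co-occur
  expect_true(row("b")$model_only)
  expect_true(row("b")$treatment_suppressed)
  # induced from nowhere: present only after treatment
  expect_true(row("c")$treatment_induced)
  expect_false(row("c")$model_only)
  expect_true(row("d")$unchanged)
  # no species is simultaneously control-only and model-only
  expect_false(any(calls$control_only & calls$model_only))
  expect_error(classify_modulation(summaries[summaries$group != "model", ]),
               "missing group")
})

test_that("recomputed significance feeds the classification", {
  set.seed(44)
  am <- make_matrix(list(
    "up [M+Na]+" = c(10, 11, 9, 30, 31, 29, 30, 32, 28),
    "flat [M+Na]+" = c(10, 11, 9, 10, 12, 8, 11, 10, 9)))
  sig <- significance_from_matrix(am)
  expect_true(sig$sig_model_vs_control[sig$species == "up [M+Na]+"])
  expect_false(sig$sig_model_vs_control[sig$species == "flat [M+Na]+"])
  calls <- classify_modulation(summarize_groups(am), sig, "recomputed")
  expect_true(calls$significantly_different_model_vs_control[
    calls$species == "up [M+Na]+"])
  # BH correction is monotone: adjusted p >= raw p
  sig_bh <- significance_from_matrix(am, correct = "BH")
  expect_true(all(sig_bh$p_model_vs_control >= sig$p_model_vs_control - 1e-12))
})

test_that("category counts add up and the empty call set is all zero", {
  summaries <- data.frame(species = "a", group = group_levels(), n = 3,
                          mean = 1, sd = 1, detectable = TRUE)
  calls <- classify_modulation(summaries)
  empty <- profile_comparison_counts(calls[0, ])
  expect_true(all(empty == 0))
})
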