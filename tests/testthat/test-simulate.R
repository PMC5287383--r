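test_that("cohort generation is deterministic for a fixed config and seed", {
  cfg <- synth_config(seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$peaklists, b$peaklists)
  expect_identical(a$behavior, b$behavior)
  c <- generate_cohort(cfg, seed = 100)
  expect_false(identical(a$peaklists, c$peaklists))
})

test_that("a noise-free cohort round-trips exactly through the pipeline", {
  cfg <- synth_config(seed = 4, sigma_log = 0, mass_jitter_ppm = 0)
  coh <- generate_cohort(cfg)
  am <- quantify_cohort(coh, method = "targeted")
  truth <- coh$truth$species
  for (i in seq_len(nrow(truth))) {
    for (g in group_levels()) {
      ids <- am$samples$sample_id[am$samples$group == g]
      got <- am$values[ids, truth$species[i]]
      want <- truth[[paste0("baseline_", g)]][i]
      expect_equal(unname(got), rep(want, length(ids)), tolerance = 1e-9)
      expect_identical(any(got > 0), truth[[paste0("detectable_", g)]][i])
    }
  }
})

test_that("presence patterns control per-group detectability by construction", {
  cfg <- synth_config(seed = 6)
  coh <- generate_cohort(cfg)
  truth <- coh$truth$species
  induced <- truth[truth$pattern == "treatment-induced", ]
  expect_false(induced$detectable_control)
  expect_false(induced$detectable_model)
  expect_true(induced$detectable_treated)
  am <- quantify_cohort(coh, method = "targeted")
  sm <- summarize_groups(am)
  det <- sm$detectable[sm$species == induced$species]
  expect_identical(det, c(FALSE, FALSE, TRUE))
})

test_that("emitted mass jitter matches the configured ppm scale", {
  cfg <- synth_config(seed = 13,
                      group_sizes = c(control = 90, model = 90, treated = 90))
  coh <- generate_cohort(cfg)
  truth <- coh$truth$species
  errs <- unlist(lapply(coh$peaklists, function(pk) {
    sp <- pk[!(abs(pk$mz - 1157.25) < 0.5 | abs(pk$mz - 1133.25) < 0.5), ]
    idx <- vapply(sp$mz, function(m) which.min(abs(truth$theoretical_mz - m)),
                  integer(1))
    ppm_error(sp$mz, truth$theoretical_mz[idx])
  }))
  expect_gt(length(errs), 1000)
  expect_lt(abs(stats::sd(errs) - cfg$mass_jitter_ppm),
            0.15 * cfg$mass_jitter_ppm)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synth_config(planted = list(species = "ghost [M+H]+",
                                           measure = "di_short", r = 0.5)),
               "planted species")
  expect_error(synth_config(planted = list(species = NULL,
                                           measure = "di_short", r = 1.2)),
               "in \\(-1, 1\\)")
  expect_error(synth_config(planted = list(species = NULL, measure = "nope",
                                           r = 0.5)),
               "planted measure")
  gl <- glycome_design("(Hex)5(HexNAc)2", "[M+Na]+", "ubiquitous")
  gl$baseline_control <- gl$baseline_model <- gl$baseline_treated <- 0
  expect_error(synth_config(glycome = gl), "absent in all groups")
})

test_that("the paper-shaped census is structural across seeds", {
  for (seed in c(1, 2)) {
    cfg <- paper_shaped_config(seed = seed)
    coh <- generate_cohort(cfg)
    am <- quantify_cohort(coh, method = "targeted")
    truth <- coh$truth$species
    sig <- data.frame(species = truth$species,
                      sig_model_vs_control = FALSE,
                      sig_treated_vs_model = truth$marked)
    counts <- profile_comparison_counts(
      classify_modulation(summarize_groups(am), sig, "markers"))
    expect_equal(unname(counts["n_species"]), 43)
    expect_equal(unname(counts["control_only"]), 9)
    expect_equal(unname(counts["model_only"]), 5)
    expect_equal(unname(counts["treatment_induced"]), 15)
    expect_equal(unname(counts["treatment_suppressed"]), 5)
    expect_equal(unname(counts["modulated_by_treatment"]), 21)
  }
})
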