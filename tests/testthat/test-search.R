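test_that("candidate enumeration finds the sodiated Man5 assignment", {
  cand <- enumerate_candidates(1257.423, "positive", search_params())
  hit <- cand[cand$composition == "(Hex)5(HexNAc)2" & cand$adduct == "[M+Na]+", ]
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$ppm_error), 1)
  # nothing admissible at low mass under default bounds
  expect_equal(nrow(enumerate_candidates(100, "positive", search_params())), 0L)
})

test_that("enumeration equals brute-force lattice search on random instances", {
  set.seed(2024)
  bounds <- c(Hex = 4, HexNAc = 3, Fuc = 2, Neu5Ac = 2, Neu5Gc = 2, S = 1)
  pos <- c("[M+Na]+", "[M+H]+")
  neg <- c("[M-H]-", "[M-2H+Na]-")
  params <- search_params(tol_ppm = 10, max_counts = bounds,
                          adducts_positive = pos, adducts_negative = neg,
                          rules = "none")
  for (i in 1:100) {
    mode <- sample(c("positive", "negative"), 1)
    mz <- stats::runif(1, 400, 1800)
    got <- enumerate_candidates(mz, mode, params)
    want <- oracle_enumerate(mz, mode, bounds,
                             if (mode == "positive") pos else neg,
                             tol_ppm = 10)
    expect_identical(sort(paste(got$composition, got$adduct)), want)
  }
})

test_that("candidates are nested under growing tolerance and ordered by |ppm|", {
  set.seed(5)
  params_of <- function(tol) search_params(tol_ppm = tol, rules = "none")
  for (mz in c(990.3, 1421.5, 1779.2)) {
    for (mode in c("positive", "negative")) {
      narrow <- enumerate_candidates(mz, mode, params_of(5))
      wide <- enumerate_candidates(mz, mode, params_of(25))
      expect_true(all(paste(narrow$composition, narrow$adduct) %in%
                        paste(wide$composition, wide$adduct)))
      expect_true(!is.unsorted(abs(wide$ppm_error)))
    }
  }
})

test_that("the default biological filter behaves as documented", {
  expect_true(biological_filter(parse_composition("(Hex)6"))$pass)
  expect_true(biological_filter(
    parse_composition("(Hex)2(HexNAc)2(Fuc)2(Neu5Ac)1"))$pass)
  r <- biological_filter(glycan_composition(Hex = 1, Neu5Ac = 4))
  expect_false(r$pass)
  expect_match(r$reason, "sialic acid without HexNAc")
  expect_false(biological_filter(
    glycan_composition(Hex = 1, HexNAc = 1, Neu5Ac = 4))$pass)
  expect_false(biological_filter(
    glycan_composition(Hex = 1, HexNAc = 2, Fuc = 3))$pass)
  expect_false(biological_filter(
    glycan_composition(HexNAc = 4))$pass)
  expect_false(biological_filter(
    glycan_composition(Hex = 3, HexNAc = 3, Neu5Ac = 1, Neu5Gc = 1))$pass)
  expect_error(biological_filter(parse_composition("(Hex)2"), rules = "nope"),
               "unknown rule-set")
})

test_that("all 99 published compositions pass the default filter", {
  for (w in c("cortex", "serum")) {
    fix <- load_fixture(w)
    for (cs in fix$composition) {
      expect_true(biological_filter(parse_composition(cs))$pass, label = cs)
    }
  }
})

test_that("peak-list assignment is deterministic and reports unassigned peaks", {
  peaks <- data.frame(mz = c(1257.423, 1257.423, 100.0),
                      intensity = c(900, 900, 10),
                      mode = "positive")
  res <- assign_peaklist(peaks, search_params())
  expect_equal(nrow(res$assignments), 2L)
  expect_identical(res$assignments$composition[1],
                   res$assignments$composition[2])
  expect_equal(nrow(res$unassigned), 1L)
  expect_match(res$unassigned$reason, "no candidate")
  empty <- assign_peaklist(peaks[0, ], search_params())
  expect_equal(nrow(empty$assignments), 0L)
  expect_equal(nrow(empty$unassigned), 0L)
})

test_that("published table rows are recovered under an absolute-Da override", {
  # printed masses are rounded (and sometimes inconsistent) beyond 10 ppm,
  # so the fixture reproduction runs with a 0.2 Da window; rows whose
  # printed mass deviates more than that from theory go to the
  # reconciliation report instead
  fix <- load_fixture("cortex")
  recon <- mass_reconciliation(fix, flag_da = 0.2)
  params <- search_params(tol_da = 0.2,
                          adducts_positive = c("[M+Na]+", "[M+K]+", "[M+H]+"),
                          adducts_negative = c("[M-H]-", "[M-2H]2-",
                                               "[M-2H+Na]-"))
  # the positive-mode rows are printed close to theory; most negative-mode
  # rows carry a systematic ~0.3-0.9 Da offset and are flagged instead
  consistent <- which(!recon$flagged)
  expect_equal(length(consistent), 21L)
  for (i in consistent) {
    mode <- adduct_mode(fix$adduct[i])
    cand <- enumerate_candidates(fix$observed_mz[i], mode, params)
    expect_true(any(cand$composition == fix$composition[i] &
                      cand$adduct == fix$adduct[i]),
                label = sprintf("row %d (%s)", fix$no[i], fix$composition[i]))
  }
  # the duplicated (Hex)8(HexNAc)2 row is mass-inconsistent and flagged
  expect_true(recon$flagged[fix$no == 23])
})
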