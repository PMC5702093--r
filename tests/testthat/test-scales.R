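test_that("self-reliance index triggers on decision-making or key ADL help", {
  expect_false(self_reliance_index(psa_example_record()))
  expect_true(self_reliance_index(psa_example_record(decision_making = 1)))
  expect_true(self_reliance_index(psa_example_record(bathing = 2)))
  # setup help only (code 1) is not "supervision or any physical help"
  expect_false(self_reliance_index(psa_example_record(bathing = 1, dressing_lower = 1)))
  # code 8 (did not occur) counts as dependent
  expect_true(self_reliance_index(psa_example_record(walking_outdoors = 8)))
})

test_that("ADL Short Scale sums the published recode of the four items", {
  expect_equal(adl_short(psa_example_record()), 0)
  expect_equal(adl_short(psa_example_record(personal_hygiene = 6, toilet_use = 6,
                                            locomotion = 6, eating = 6)), 16)
  # mixed vector checked against the recode enumerated independently
  rec <- psa_example_record(personal_hygiene = 2, toilet_use = 3, locomotion = 0, eating = 6)
  expect_equal(adl_short(rec),
               sum(bf_recode(c(2, 3, 0, 6))))
  # every single-item code maps exactly as the shipped table says
  for (code in c(0:6, 8)) {
    expect_equal(adl_short(psa_example_record(eating = code)),
                 unname(bf_recode(code)))
  }
})

test_that("ADL Hierarchy distinguishes early-loss from late-loss dependence", {
  expect_equal(adl_hierarchy(psa_example_record()), 0L)
  # total dependence in all four items
  expect_equal(adl_hierarchy(psa_example_record(personal_hygiene = 6, toilet_use = 6,
                                                locomotion = 6, eating = 6)), 6L)
  # dependent in a late-loss ADL only
  expect_equal(adl_hierarchy(psa_example_record(eating = 6)), 5L)
  # extensive help in a late-loss ADL outranks extensive help in early-loss
  expect_equal(adl_hierarchy(psa_example_record(eating = 4)), 4L)
  expect_equal(adl_hierarchy(psa_example_record(personal_hygiene = 4)), 3L)
  expect_equal(adl_hierarchy(psa_example_record(locomotion = 2)), 1L)
  expect_equal(adl_hierarchy(psa_example_record(locomotion = 3)), 2L)
})

test_that("ADL Hierarchy is monotone under exhaustive single-item escalation", {
  codes <- c(0:6, 8)
  grid <- expand.grid(personal_hygiene = codes, toilet_use = codes,
                      locomotion = codes, eating = codes)
  base <- psa_example_record()[rep(1, nrow(grid)), ]
  for (it in names(grid)) base[[it]] <- grid[[it]]
  h0 <- adl_hierarchy(base)
  for (it in names(grid)) {
    idx <- match(grid[[it]], codes)
    can_raise <- idx < length(codes)
    raised <- base
    raised[[it]] <- codes[pmin(idx + 1L, length(codes))]
    h1 <- adl_hierarchy(raised)
    expect_true(all(h1[can_raise] >= h0[can_raise]),
                info = paste("raising", it, "lowered the hierarchy"))
  }
})

test_that("CPS grades cognitive impairment on the published structure", {
  expect_equal(cps(psa_example_record()), 0L)
  expect_equal(cps(psa_example_record(decision_making = 4, eating = 6)), 6L)
  expect_equal(cps(psa_example_record(decision_making = 4)), 5L)
  # one impairment -> 1; two mild -> 2; severe decision-making deepens
  expect_equal(cps(psa_example_record(decision_making = 1)), 1L)
  expect_equal(cps(psa_example_record(decision_making = 1, short_term_memory_ok = 0)), 2L)
  expect_equal(cps(psa_example_record(decision_making = 2, short_term_memory_ok = 0)), 3L)
  expect_equal(cps(psa_example_record(decision_making = 2, short_term_memory_ok = 0,
                                      making_self_understood = 2)), 4L)
  # mild-impairment band is reachable at both its end points
  expect_true(all(c(1L, 2L) %in% c(cps(psa_example_record(making_self_understood = 1)),
                                   cps(psa_example_record(making_self_understood = 1,
                                                          short_term_memory_ok = 0)))))
})

test_that("IADL difficulty is the sum of the three item codes", {
  expect_equal(iadl_difficulty(psa_example_record()), 0)
  expect_equal(iadl_difficulty(psa_example_record(meal_preparation = 2, ordinary_housework = 2,
                                                  phone_use = 2)), 6)
  expect_equal(iadl_difficulty(psa_example_record(meal_preparation = 1, ordinary_housework = 2)), 3)
})

test_that("scale profile equals the per-calculator results and is deterministic", {
  rec <- psa_example_record(bathing = 3, personal_hygiene = 2, eating = 4,
                            decision_making = 1, meal_preparation = 2)
  p <- scale_profile(rec)
  expect_equal(p$self_reliance_impaired, as.integer(self_reliance_index(rec)))
  expect_equal(p$adl_short, adl_short(rec))
  expect_equal(p$adl_hierarchy, adl_hierarchy(rec))
  expect_equal(p$cps, cps(rec))
  expect_equal(p$iadl_difficulty, iadl_difficulty(rec))
  expect_identical(p, scale_profile(rec))
  # untouched SRI items: pure IADL difficulty leaves everything else at zero
  p2 <- scale_profile(psa_example_record(meal_preparation = 2, ordinary_housework = 2,
                                         phone_use = 2))
  expect_equal(unlist(p2), c(self_reliance_impaired = 0, adl_short = 0,
                             adl_hierarchy = 0, cps = 0, iadl_difficulty = 6))
})

test_that("all scales stay in range and short scales are monotone on random records", {
  set.seed(2024)
  codes <- c(0:6, 8)
  n <- 400
  rec <- psa_example_record()[rep(1, n), ]
  for (it in c("bathing", "personal_hygiene", "dressing_upper", "dressing_lower",
               "walking_indoors", "walking_outdoors", "locomotion", "toilet_use",
               "eating", "bed_mobility")) rec[[it]] <- sample(codes, n, TRUE)
  rec$decision_making <- sample(0:4, n, TRUE)
  rec$short_term_memory_ok <- sample(0:1, n, TRUE)
  rec$making_self_understood <- sample(0:4, n, TRUE)
  for (it in c("meal_preparation", "ordinary_housework", "phone_use"))
    rec[[it]] <- sample(0:2, n, TRUE)
  p <- scale_profile(rec)
  expect_true(all(p$adl_short >= 0 & p$adl_short <= 16))
  expect_true(all(p$adl_hierarchy >= 0 & p$adl_hierarchy <= 6))
  expect_true(all(p$cps >= 0 & p$cps <= 6))
  expect_true(all(p$iadl_difficulty >= 0 & p$iadl_difficulty <= 6))
  # monotonicity of the additive scales under raising one contributing item
  raised <- rec
  raised$eating <- codes[pmin(match(rec$eating, codes) + 1L, length(codes))]
  expect_true(all(adl_short(raised) >= p$adl_short))
  raised2 <- rec
  raised2$phone_use <- pmin(rec$phone_use + 1, 2)
  expect_true(all(iadl_difficulty(raised2) >= p$iadl_difficulty))
  # SRI consistency: hierarchy >= 1 driven by personal hygiene >= 2 implies impaired
  driven <- p$adl_hierarchy >= 1 & rec$personal_hygiene >= 2
  expect_true(all(p$self_reliance_impaired[driven] == 1))
})
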