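# values each classifier input takes in the discretised sweep: every
# cut-relevant level plus the extremes of its declared range
sweep_grid <- function() {
  expand.grid(
    self_reliance_impaired = 0:1,
    iadl_difficulty = c(0, 1, 2, 4, 5, 6),
    adl_short = c(0, 2, 3, 10, 11, 16),
    dressing_upper = c(0, 1, 2, 6, 8),
    decision_making = c(0, 1, 4),
    cps = c(0, 2, 3, 6),
    unstable_conditions = 0:1,
    bladder_incontinence = c(0, 1, 2, 5),
    bowel_incontinence = c(0, 1, 2, 5),
    making_self_understood = c(0, 1, 2, 4),
    caregiver_distress = 0:1)
}

test_that("the bundled reference tree loads with six top-level groups", {
  tree <- psa_reference_tree()
  g <- tree_groups(tree)
  expect_setequal(g, c("1A", "1B", "1C", "2", "3", "4", "5", "6"))
  expect_setequal(unique(substr(g, 1, 1)), as.character(1:6))
})

test_that("structural defects in tree JSON are rejected with node ids", {
  tree <- psa_reference_tree()
  # cycle: point a leaf's parent back at the root
  bad <- unclass(tree)
  bad$nodes$n_sri0_iadl_hi$children <- c("l_1b", "n_root")
  expect_error(load_tree(bad), "n_root")
  # dangling child
  bad2 <- unclass(tree)
  bad2$nodes$n_sri0_iadl$children <- c("l_1a", "nowhere")
  expect_error(load_tree(bad2), "nowhere")
  # unreachable node
  bad3 <- unclass(tree)
  bad3$nodes$extra <- list(id = "extra", type = "leaf", group = "2")
  expect_error(load_tree(bad3), "unreachable")
})

test_that("tree specifications round-trip through JSON", {
  tree <- psa_reference_tree()
  f <- withr::local_tempfile(fileext = ".json")
  save_tree(tree, f)
  back <- load_tree(f)
  expect_equal(back$root, tree$root)
  expect_equal(names(back$nodes), names(tree$nodes))
  for (id in names(tree$nodes)) expect_equal(back$nodes[[id]], tree$nodes[[id]])
})

test_that("classification follows the published narrative paths", {
  # fully independent: index not triggered, minimal IADL difficulty
  expect_equal(classify(psa_example_record())$display, "1A")
  # index not triggered, great IADL difficulty
  expect_equal(classify(psa_example_record(meal_preparation = 2, ordinary_housework = 2,
                                           phone_use = 2))$display, "1C")
  # maximal ADL impairment + weekly bowel incontinence + caregiver distress
  r6 <- psa_example_record(personal_hygiene = 6, toilet_use = 6, locomotion = 6,
                           eating = 6, bowel_incontinence = 2, caregiver_distress = 1)
  expect_equal(classify(r6)$display, "6")
  # low ADL impairment + help dressing upper body + decision-making difficulty
  r3 <- psa_example_record(bathing = 2, dressing_upper = 2, decision_making = 1)
  expect_equal(classify(r3)$display, "3")
})

test_that("every discretised input reaches exactly one terminal and the label set is complete", {
  grid <- sweep_grid()
  res <- classify_cohort(grid, psa_reference_tree())
  expect_equal(nrow(res), nrow(grid))
  expect_setequal(unique(res$display), c("1A", "1B", "1C", "2", "3", "4", "5", "6"))
  expect_setequal(unique(res$top_level), 1:6)
  expect_setequal(unique(res$sublevel[res$top_level == 1]), c("A", "B", "C"))
  expect_true(all(is.na(res$sublevel[res$top_level > 1])))
})

test_that("worsening a single need indicator never lowers the top-level group", {
  grid <- sweep_grid()
  tree <- psa_reference_tree()
  base <- classify_cohort(grid, tree)$top_level
  worsen <- list(
    adl_short = function(g) { g$adl_short <- pmin(g$adl_short + 3, 16); g },
    bladder_incontinence = function(g) { g$bladder_incontinence <- pmin(g$bladder_incontinence + 2, 5); g },
    bowel_incontinence = function(g) { g$bowel_incontinence <- pmin(g$bowel_incontinence + 2, 5); g },
    caregiver_distress = function(g) { g$caregiver_distress <- 1; g },
    unstable_conditions = function(g) { g$unstable_conditions <- 1; g },
    iadl_difficulty = function(g) { g$iadl_difficulty <- pmin(g$iadl_difficulty + 2, 6); g },
    self_reliance_impaired = function(g) { g$self_reliance_impaired <- 1; g })
  for (nm in names(worsen)) {
    after <- classify_cohort(worsen[[nm]](grid), tree)$top_level
    expect_true(all(after >= base), info = paste("worsening", nm, "lowered a group"))
  }
})

test_that("cohort classification aggregates and reports the unclassifiable", {
  expect_equal(nrow(classify_cohort(psa_example_record()[0, ])), 0)
  same <- psa_example_record()[rep(1, 25), ]
  same$person_id <- sprintf("P%02d", 1:25)
  res <- classify_cohort(same)
  expect_equal(unname(as.numeric(attr(res, "distribution")["1A"])), 100)
  # missing input under the reject policy
  with_na <- rbind(psa_example_record(), psa_example_record(person_id = "P2"))
  with_na$decision_making[2] <- NA
  res2 <- classify_cohort(with_na)
  expect_equal(nrow(res2), 1)
  un <- attr(res2, "unclassified")
  expect_equal(un$row, 2L)
  expect_match(un$reason, "decision_making|cps|self_reliance")
  # the impute-independent policy classifies the same row
  res3 <- classify_cohort(with_na, missing_policy = "impute_independent")
  expect_equal(nrow(res3), 2)
  expect_error(classify(with_na[2, ]), "could not be classified")
})

test_that("classification is a pure function of record and tree version", {
  set.seed(5)
  sim <- generate_cohort(200, seed = 9)
  a <- classify_cohort(sim$assessments)
  b <- classify_cohort(sim$assessments)
  expect_identical(a, b)
  expect_true(all(a$tree_version == psa_reference_tree()$version))
})
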