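test_that("the F statistic matches the linear-model oracle and its degenerate cases", {
  # no between-group variance
  expect_equal(one_way_f(c(5, 5, 5, 5), c("a", "a", "b", "b"))$F, 0)
  expect_equal(one_way_f(c(5, 5, 5, 5), c("a", "a", "b", "b"))$p, 1)
  r <- one_way_f(c(1, 2, 3, 1, 2, 3), rep(c("L", "R"), each = 3))
  expect_equal(r$F, 0)
  # hand-sized instance against anova(lm())
  y <- c(0, 0, 1, 2, 3, 3)
  g <- rep(c("L", "R"), each = 3)
  o <- bf_anova(y, g)
  r2 <- one_way_f(y, g)
  expect_equal(r2$F, o$F, tolerance = 1e-12)
  expect_equal(r2$p, o$p, tolerance = 1e-12)
  expect_error(one_way_f(1:5, rep("a", 5)), "2 non-empty groups")
})

test_that("Bonferroni adjustment multiplies and caps, and partition counts are exact", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1.0)
  expect_equal(n_candidate_partitions(7, allow_multiway = FALSE), 6L)     # c - 1 binary cuts
  expect_equal(n_candidate_partitions(7, allow_multiway = TRUE), 6L + choose(6, 2))
  expect_equal(n_candidate_partitions(1), 0L)
  # counted m on real data: one ordinal feature with c observed levels
  set.seed(3)
  d <- data.frame(x = rep(0:4, each = 40))
  y <- d$x + rnorm(200)
  sp <- best_split(d, y, psa_control(min_leaf = 20, allow_multiway = FALSE))
  expect_equal(sp$m, 4L)
})

test_that("best_split honours the minimum-leaf precondition", {
  set.seed(4)
  d <- data.frame(x = sample(0:6, 150, TRUE))
  y <- d$x + rnorm(150)
  expect_null(best_split(d, y, psa_control(min_leaf = 100)))
})

test_that("best_split recovers a planted step and matches exhaustive search on tiny nodes", {
  set.seed(8)
  n <- 2000
  d <- data.frame(x = sample(0:6, n, TRUE), z = sample(0:6, n, TRUE))
  y <- as.numeric(d$x >= 3) + rnorm(n, sd = 0.5)
  sp <- best_split(d, y, psa_control(min_leaf = 100))
  expect_equal(sp$variable, "x")
  expect_equal(sp$cuts, 3)
  # oracle equivalence on <= 12-row single-feature instances
  for (rep in 1:20) {
    m <- sample(8:12, 1)
    x <- sample(0:3, m, TRUE)
    yy <- rnorm(m) + x
    ours <- best_split(data.frame(x = x), yy, psa_control(min_leaf = 2, alpha = 0.5))
    oracle <- bf_best_split(x, yy, min_leaf = 2, alpha = 0.5)
    if (is.null(oracle)) {
      expect_null(ours)
    } else {
      expect_equal(ours$cuts, oracle$cuts)
      expect_equal(ours$p_adj, oracle$p_adj, tolerance = 1e-10)
    }
  }
})

test_that("pure-noise targets rarely admit a split at alpha = 0.05", {
  set.seed(12)
  hits <- 0
  for (r in 1:60) {
    d <- data.frame(x = sample(0:6, 300, TRUE))
    y <- rnorm(300)
    if (!is.null(best_split(d, y, psa_control(min_leaf = 50)))) hits <- hits + 1
  }
  expect_lte(hits / 60, 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("growth respects depth, leaf size, significance and the forced first variable", {
  set.seed(21)
  n <- 1200
  d <- data.frame(adl = sample(0:6, n, TRUE), age = sample(60:95, n, TRUE),
                  cps = sample(0:6, n, TRUE))
  y <- 2 * (d$adl >= 3) + 1 * (d$cps >= 4) + rnorm(n, sd = 0.6)

  t1 <- grow_tree(d, y, psa_control(max_depth = 1, min_leaf = 100))
  expect_equal(length(t1$nodes), 1L)         # depth cap 1: root only

  t2 <- grow_tree(d, y, psa_control(max_depth = 2, min_leaf = 100))
  expect_lte(length(t2$nodes), 4L)           # root split at most

  full <- grow_tree(d, y, psa_control(min_leaf = 100))
  leaves <- Filter(function(nd) nd$type == "leaf", full$nodes)
  expect_true(all(vapply(leaves, `[[`, numeric(1), "n") >= 100))
  splits <- Filter(function(nd) nd$type == "split", full$nodes)
  expect_true(all(vapply(splits, `[[`, numeric(1), "p_adj") < 0.05))

  forced <- grow_tree(d, y, psa_control(min_leaf = 100, forced_first_variable = "age"))
  expect_equal(forced$nodes[[forced$root]]$variable, "age")
  expect_error(grow_tree(d, y, psa_control(forced_first_variable = "nope")), "nope")
})

test_that("identical data and parameters give identical serialised trees", {
  set.seed(31)
  d <- data.frame(a = sample(0:5, 600, TRUE), b = sample(0:5, 600, TRUE))
  y <- d$a + rnorm(600)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_tree(grow_tree(d, y, psa_control(min_leaf = 60)), f1)
  save_tree(grow_tree(d, y, psa_control(min_leaf = 60)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("raising min_leaf or lowering alpha never deepens the tree", {
  depth_of <- function(tree) {
    d <- function(id, k) {
      node <- tree$nodes[[id]]
      if (node$type == "leaf") return(k)
      max(vapply(node$children, d, numeric(1), k = k + 1))
    }
    d(tree$root, 1)
  }
  set.seed(41)
  d <- data.frame(a = sample(0:6, 900, TRUE), b = sample(0:6, 900, TRUE))
  y <- d$a + 0.5 * d$b + rnorm(900)
  base <- depth_of(grow_tree(d, y, psa_control(min_leaf = 60, alpha = 0.05)))
  expect_lte(depth_of(grow_tree(d, y, psa_control(min_leaf = 150, alpha = 0.05))), base)
  expect_lte(depth_of(grow_tree(d, y, psa_control(min_leaf = 60, alpha = 0.001))), base)
})

test_that("leaf collapsing merges by mean with strictly increasing group means", {
  # exact tie merge: {1, 1, 5} into 2 groups
  set.seed(51)
  d <- data.frame(x = rep(c(0, 1, 2), each = 50))
  y <- rep(c(1, 1, 5), each = 50) + rnorm(150, sd = 1e-6)
  tr <- grow_tree(d, y, psa_control(min_leaf = 40, alpha = 0.5))
  tr2 <- collapse_leaves(tr, k = 2)
  leaves <- Filter(function(nd) nd$type == "leaf", tr2$nodes)
  grp <- vapply(leaves, `[[`, character(1), "group")
  mu <- vapply(leaves, `[[`, numeric(1), "mean")
  expect_equal(unname(grp[order(mu)]), c("1", "1", "2"))
  gm <- attr(tr2, "group_means")
  expect_true(all(diff(gm) > 0))
  # identity collapse
  tr3 <- collapse_leaves(tr, k = length(leaves))
  expect_equal(length(unique(vapply(Filter(function(nd) nd$type == "leaf", tr3$nodes),
                                    `[[`, character(1), "group"))), length(leaves))
  expect_error(collapse_leaves(tr, k = 10), "terminal nodes")
})

test_that("the derivation/validation partition is a seeded 70/30 split", {
  d <- data.frame(i = 1:1000)
  p1 <- partition_cohort(d, prop = 0.7, seed = 99)
  p2 <- partition_cohort(d, prop = 0.7, seed = 99)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$derivation), 700)
  expect_equal(nrow(p1$validation), 300)
  expect_setequal(c(p1$derivation$i, p1$validation$i), d$i)
})
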