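# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take different computational routes (lm/anova, manual
# interpolation, exhaustive enumeration) from the package code.

# one-way ANOVA F and p through R's linear-model machinery
bf_anova <- function(values, labels) {
  a <- stats::anova(stats::lm(values ~ factor(labels)))
  list(F = a[1, "F value"], p = a[1, "Pr(>F)"])
}

# R-squared of predicting each observation with its group mean, by raw sums
bf_r2 <- function(groups, hours) {
  sst <- sum((hours - mean(hours))^2)
  sse <- 0
  for (g in unique(groups)) {
    h <- hours[groups == g]
    sse <- sse + sum((h - mean(h))^2)
  }
  1 - sse / sst
}

bf_cv <- function(groups, hours) {
  res <- numeric(length(hours))
  for (g in unique(groups)) {
    sel <- groups == g
    res[sel] <- hours[sel] - mean(hours[sel])
  }
  100 * sqrt(mean(res^2)) / mean(hours)
}

# linear-interpolation quantile written out by hand (matches type 7)
bf_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive best split for a single ordinal feature: every binary cut and
# every contiguous 3-way partition, p-values from lm/anova, node-level
# Bonferroni, smallest adjusted p (binary preferred, then smaller cut)
bf_best_split <- function(x, y, min_leaf, alpha = 0.05, allow_multiway = TRUE) {
  lv <- sort(unique(x))
  cands <- list()
  for (j in seq_along(lv)[-1]) {
    lab <- ifelse(x < lv[j], "L", "R")
    if (min(table(lab)) < min_leaf) next
    fp <- bf_anova(y, lab)
    cands[[length(cands) + 1]] <- list(cuts = lv[j], arity = 2, p = fp$p)
  }
  if (allow_multiway && length(lv) >= 3) {
    for (i in 2:(length(lv) - 1)) {
      for (j in (i + 1):length(lv)) {
        lab <- ifelse(x < lv[i], "A", ifelse(x < lv[j], "B", "C"))
        if (length(unique(lab)) < 3 || min(table(lab)) < min_leaf) next
        fp <- bf_anova(y, lab)
        cands[[length(cands) + 1]] <- list(cuts = c(lv[i], lv[j]), arity = 3, p = fp$p)
      }
    }
  }
  m <- psalloc::n_candidate_partitions(length(lv), allow_multiway)
  if (!length(cands)) return(NULL)
  for (k in seq_along(cands)) cands[[k]]$p_adj <- min(1, m * cands[[k]]$p)
  ord <- order(vapply(cands, `[[`, numeric(1), "p_adj"),
               vapply(cands, `[[`, numeric(1), "arity"),
               vapply(cands, function(c) c$cuts[1], numeric(1)))
  best <- cands[[ord[1]]]
  if (best$p_adj >= alpha) return(NULL)
  best
}

# the ADL recode written out directly from the shipped table semantics
bf_recode <- function(code) c(`0` = 0, `1` = 0, `2` = 1, `3` = 2, `4` = 3,
                              `5` = 3, `6` = 4, `8` = 4)[as.character(code)]
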