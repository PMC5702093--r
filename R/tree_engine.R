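#' One-way ANOVA F statistic for a candidate partition
#'
#' Variance-reduction splitting criterion: the standard one-way ANOVA F with
#' (k-1, n-k) degrees of freedom for a numeric target partitioned into k
#' groups, and its upper-tail p-value. A partition with zero total variance is
#' defined to have F = 0, p = 1 (no variance to reduce).
#'
#' @param values Numeric target vector.
#' @param labels Partition assignment (factor or vector), one label per value.
#' @return Named list with `F`, `p`, `df1`, `df2`.
#' @examples
#' one_way_f(c(0, 0, 1, 2, 3, 3), rep(c("L", "R"), each = 3))
#' @export
one_way_f <- function(values, labels) {
  labels <- as.character(labels)
  if (anyNA(values) || anyNA(labels)) stop("values and labels must be complete", call. = FALSE)
  n_g <- table(labels)
  k <- length(n_g)
  n <- length(values)
  if (k < 2L || any(n_g == 0L)) stop("need at least 2 non-empty groups", call. = FALSE)
  if (n <= k) stop("need more observations than groups", call. = FALSE)
  grand <- mean(values)
  sst <- sum((values - grand)^2)
  if (sst <= 0) return(list(F = 0, p = 1, df1 = k - 1L, df2 = n - k))
  means <- tapply(values, labels, mean)
  ssb <- sum(as.numeric(n_g) * (means - grand)^2)
  ssw <- max(sst - ssb, 0)
  f <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE), df1 = k - 1L, df2 = n - k)
}

#' Bonferroni adjustment for multiple candidate partitions
#'
#' @param p Raw p-value(s) in \[0, 1\].
#' @param m Number of candidate partitions tested (>= 1).
#' @return `min(1, m * p)`, vectorised over `p`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Number of candidate partitions for an ordinal variable
#'
#' For a variable with `c` distinct observed levels there are `c - 1`
#' admissible binary cuts; when contiguous 3-way partitions are allowed,
#' `choose(c - 1, 2)` more. This per-variable count feeds the node-level
#' Bonferroni multiplicity.
#'
#' @param n_levels Number of distinct observed values.
#' @param allow_multiway Count contiguous 3-way partitions as well?
#' @return Integer count (0 when fewer than 2 levels).
#' @export
n_candidate_partitions <- function(n_levels, allow_multiway = TRUE) {
  if (n_levels < 2L) return(0L)
  m <- n_levels - 1L
  if (allow_multiway && n_levels >= 3L) m <- m + choose(n_levels - 1L, 2L)
  as.integer(m)
}

#' Growth parameters for tree derivation
#'
#' Defaults mirror the derivation protocol: F-test splitting, binary splits
#' preferred with contiguous 3-way splits allowed, at most six levels in the
#' tree structure, at least 100 observations in any terminal node, and
#' Bonferroni-adjusted significance at alpha = 0.05 on every split.
#'
#' @param max_depth Maximum number of levels in the tree (root = level 1).
#' @param min_leaf Minimum observations in any terminal node.
#' @param alpha Significance level applied to Bonferroni-adjusted p-values.
#' @param allow_multiway Consider contiguous 3-way partitions (binary is
#'   preferred on ties)?
#' @param forced_first_variable Optional variable name forced as the root
#'   split (interactive growth); the forced split is an explicit analyst
#'   override and bypasses the significance gate but still respects
#'   `min_leaf`.
#' @param seed Integer recorded with the fit; splitting itself is
#'   deterministic (ties are broken by fixed rules) so the seed only pins
#'   provenance.
#' @return A list of class `psa_control`.
#' @export
psa_control <- function(max_depth = 6L, min_leaf = 100L, alpha = 0.05,
                        allow_multiway = TRUE, forced_first_variable = NULL,
                        seed = 1L) {
  stopifnot(max_depth >= 1, min_leaf >= 1, alpha > 0, alpha < 1)
  structure(list(max_depth = as.integer(max_depth), min_leaf = as.integer(min_leaf),
                 alpha = alpha, allow_multiway = isTRUE(allow_multiway),
                 forced_first_variable = forced_first_variable,
                 seed = as.integer(seed)),
            class = "psa_control")
}

# Evaluate all candidate partitions of one ordinal/numeric variable at a node.
# Returns list(candidates = data frame, m = partition count). Each candidate
# row: cut1, cut2 (NA for binary), k, F, p, admissible.
.var_candidates <- function(x, y, min_leaf, allow_multiway) {
  keep <- !is.na(x)          # rows missing this variable do not enter its evaluation
  x <- x[keep]; y <- y[keep]
  lv <- sort(unique(x))
  c_lev <- length(lv)
  m <- n_candidate_partitions(c_lev, allow_multiway)
  if (c_lev < 2L) return(list(candidates = NULL, m = 0L))

  n <- length(y)
  grand <- mean(y)
  sst <- sum((y - grand)^2)
  lev_n <- as.numeric(rowsum(rep(1, n), match(x, lv)))
  lev_s <- as.numeric(rowsum(y, match(x, lv)))
  cn <- cumsum(lev_n); cs <- cumsum(lev_s)

  res <- vector("list", m)
  ri <- 0L
  f_of <- function(ns, ss) {
    # ns: group sizes, ss: group sums
    if (sst <= 0) return(c(0, 1))
    ssb <- sum(ss^2 / ns) - n * grand^2
    ssb <- max(ssb, 0)
    k <- length(ns)
    ssw <- max(sst - ssb, 0)
    f <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))
    c(f, stats::pf(f, k - 1, n - k, lower.tail = FALSE))
  }
  for (j in seq_len(c_lev - 1L)) {
    nl <- cn[j]; nr <- n - nl
    fp <- f_of(c(nl, nr), c(cs[j], cs[c_lev] - cs[j]))
    ri <- ri + 1L
    res[[ri]] <- c(lv[j + 1L], NA, 2, fp[1], fp[2], as.numeric(nl >= min_leaf && nr >= min_leaf))
  }
  if (allow_multiway && c_lev >= 3L) {
    for (i in seq_len(c_lev - 2L)) {
      for (j in seq((i + 1L), c_lev - 1L)) {
        n1 <- cn[i]; n2 <- cn[j] - cn[i]; n3 <- n - cn[j]
        fp <- f_of(c(n1, n2, n3), c(cs[i], cs[j] - cs[i], cs[c_lev] - cs[j]))
        ri <- ri + 1L
        res[[ri]] <- c(lv[i + 1L], lv[j + 1L], 3, fp[1], fp[2],
                       as.numeric(min(n1, n2, n3) >= min_leaf))
      }
    }
  }
  cand <- as.data.frame(do.call(rbind, res[seq_len(ri)]))
  names(cand) <- c("cut1", "cut2", "k", "F", "p", "admissible")
  list(candidates = cand, m = m)
}

#' Select the best split at a node
#'
#' Evaluates every candidate partition (all binary cuts, plus contiguous
#' 3-way partitions when allowed) of every candidate variable, Bonferroni
#' adjusts each raw F-test p-value by the total number of candidate
#' partitions at the node, and returns the admissible candidate with the
#' smallest adjusted p-value, provided it is below `alpha`. Ties are broken
#' deterministically: binary before multi-way, then smaller first cut, then
#' lexicographic variable name.
#'
#' @param data Data frame of candidate split variables (numeric/ordinal).
#' @param target Numeric target vector, same length as `nrow(data)`.
#' @param control A [psa_control()] object.
#' @param candidate_vars Variables to consider; defaults to all columns.
#' @param ignore_alpha Internal: return the best admissible candidate even if
#'   not significant (used for forced splits).
#' @return A list of class `psa_split` with fields `variable`, `cuts`,
#'   `arity`, `F`, `p_raw`, `p_adj`, `m` (node-level multiplicity), or `NULL`
#'   when no admissible significant candidate exists.
#' @export
best_split <- function(data, target, control = psa_control(),
                       candidate_vars = names(data), ignore_alpha = FALSE) {
  n <- length(target)
  if (n < 2L * control$min_leaf) return(NULL)
  per_var <- lapply(candidate_vars, function(v)
    .var_candidates(data[[v]], target, control$min_leaf, control$allow_multiway))
  names(per_var) <- candidate_vars
  m_node <- sum(vapply(per_var, `[[`, integer(1), "m"))
  if (m_node == 0L) return(NULL)

  best <- NULL
  for (v in candidate_vars) {
    cand <- per_var[[v]]$candidates
    if (is.null(cand)) next
    cand <- cand[cand$admissible == 1, , drop = FALSE]
    if (!nrow(cand)) next
    cand$p_adj <- bonferroni(cand$p, m_node)
    for (i in seq_len(nrow(cand))) {
      ch <- list(variable = v, cuts = stats::na.omit(c(cand$cut1[i], cand$cut2[i])),
                 arity = cand$k[i], F = cand$F[i], p_raw = cand$p[i],
                 p_adj = cand$p_adj[i], m = m_node)
      if (is.null(best) || .split_better(ch, best)) best <- ch
    }
  }
  if (is.null(best)) return(NULL)
  if (!ignore_alpha && best$p_adj >= control$alpha) return(NULL)
  attributes(best$cuts) <- NULL
  class(best) <- "psa_split"
  best
}

# Deterministic ordering of split candidates: smaller adjusted p, then binary
# before multi-way, then smaller first cut, then variable name.
.split_better <- function(a, b) {
  if (a$p_adj != b$p_adj) return(a$p_adj < b$p_adj)
  if (a$arity != b$arity) return(a$arity < b$arity)
  if (a$cuts[1] != b$cuts[1]) return(a$cuts[1] < b$cuts[1])
  a$variable < b$variable
}

#' Grow a variance-reduction decision tree
#'
#' Recursive partitioning of a numeric target by ordinal assessment
#' variables: at each node the best Bonferroni-adjusted F-test split is taken
#' (see [best_split()]) until the depth cap, the minimum-leaf constraint or
#' the significance gate stops growth. Terminal nodes are left ungrouped;
#' [collapse_leaves()] assigns ordered need groups.
#'
#' @param data Data frame of candidate split variables.
#' @param target Numeric target vector (e.g. weekly billed hours).
#' @param control A [psa_control()] object.
#' @return A `psa_treespec` whose leaves carry `n` and `mean` statistics.
#' @export
grow_tree <- function(data, target, control = psa_control()) {
  stopifnot(nrow(data) == length(target), nrow(data) > 0, is.numeric(target))
  forced <- control$forced_first_variable
  if (!is.null(forced) && !forced %in% names(data))
    stop("forced first variable '", forced, "' not in data", call. = FALSE)

  nodes <- list()
  counter <- 0L
  new_id <- function() { counter <<- counter + 1L; sprintf("n%03d", counter) }

  build <- function(idx, depth) {
    id <- new_id()
    y <- target[idx]
    sp <- NULL
    if (depth < control$max_depth) {
      if (depth == 1L && !is.null(forced)) {
        sp <- best_split(data[idx, , drop = FALSE], y, control,
                         candidate_vars = forced, ignore_alpha = TRUE)
      } else {
        sp <- best_split(data[idx, , drop = FALSE], y, control)
      }
    }
    if (is.null(sp)) {
      nodes[[id]] <<- list(id = id, type = "leaf", group = NULL,
                           n = length(idx), mean = mean(y))
      return(id)
    }
    x <- data[[sp$variable]][idx]
    if (anyNA(x)) {            # rows missing the split variable leave the tree here
      dropped <- sum(is.na(x))
      message("node ", id, ": ", dropped, " row(s) missing '", sp$variable, "' excluded")
      idx <- idx[!is.na(x)]; x <- x[!is.na(x)]
    }
    assigned <- rep(length(sp$cuts) + 1L, length(idx))
    for (j in rev(seq_along(sp$cuts))) assigned[x < sp$cuts[j]] <- j
    children <- character(length(sp$cuts) + 1L)
    # reserve the parent's position before recursing so ids read top-down
    nodes[[id]] <<- list(id = id, type = "split", variable = sp$variable,
                         cuts = sp$cuts, children = NULL,
                         n = length(idx), F = sp$F, p_adj = sp$p_adj, m = sp$m)
    for (j in seq_along(children)) children[j] <- build(idx[assigned == j], depth + 1L)
    nodes[[id]]$children <<- children
    id
  }
  root <- build(seq_len(nrow(data)), 1L)

  structure(list(version = "psalloc-derived-1",
                 provenance = sprintf("grow_tree(max_depth=%d, min_leaf=%d, alpha=%g, multiway=%s, seed=%d)",
                                      control$max_depth, control$min_leaf, control$alpha,
                                      control$allow_multiway, control$seed),
                 target = NA_character_, root = root, nodes = nodes),
            class = "psa_treespec")
}

#' Collapse terminal nodes into ordered need groups
#'
#' Mirrors the manual step in which terminal nodes with similar average hours
#' are combined into higher-level groups: leaves are sorted by mean target
#' value and partitioned into `k` contiguous groups minimising the
#' within-group (leaf-size weighted) sum of squares by dynamic programming.
#' Groups are labelled "1".."k" in order of increasing mean.
#'
#' @param tree A `psa_treespec` grown by [grow_tree()].
#' @param data,target Optional data used to (re)compute leaf means; when
#'   omitted the leaf statistics stored at growth time are used.
#' @param k Number of groups (analyst's choice; must not exceed the number of
#'   leaves).
#' @return The tree with every leaf's `group` set; attribute
#'   `"group_means"` holds the ordered group means.
#' @export
collapse_leaves <- function(tree, k, data = NULL, target = NULL) {
  leaf_ids <- names(tree$nodes)[vapply(tree$nodes, function(n) n$type == "leaf", logical(1))]
  if (k > length(leaf_ids))
    stop("requested ", k, " groups but tree has only ", length(leaf_ids), " terminal nodes",
         call. = FALSE)
  if (!is.null(data)) {
    leaf_of <- .route(data, tree)
    mu <- tapply(target, leaf_of, mean)
    nn <- tapply(target, leaf_of, length)
    if (!all(leaf_ids %in% names(mu)))
      stop("data does not reach every terminal node; cannot recompute leaf means", call. = FALSE)
    means <- as.numeric(mu[leaf_ids]); sizes <- as.numeric(nn[leaf_ids])
  } else {
    means <- vapply(tree$nodes[leaf_ids], function(n) n$mean %||% NA_real_, numeric(1))
    sizes <- vapply(tree$nodes[leaf_ids], function(n) n$n %||% NA_real_, numeric(1))
    if (anyNA(means)) stop("tree carries no leaf means; supply data and target", call. = FALSE)
  }

  ord <- order(means)
  grp_sorted <- .cluster_1d(means[ord], sizes[ord], k)
  group <- integer(length(means))
  group[ord] <- grp_sorted
  for (i in seq_along(leaf_ids)) tree$nodes[[leaf_ids[i]]]$group <- as.character(group[i])

  gm <- tapply(rep(means, 1) * sizes, group, sum) / tapply(sizes, group, sum)
  gm <- as.numeric(gm[order(as.integer(names(gm)))])
  if (any(diff(gm) <= 0))
    warning("collapsed group means are not strictly increasing (tied leaf means)")
  attr(tree, "group_means") <- gm
  tree
}

# Optimal contiguous partition of sorted weighted values into k groups
# minimising within-group weighted SS (Fisher's exact 1-D clustering DP).
.cluster_1d <- function(v, w, k) {
  n <- length(v)
  cw <- cumsum(w); cs <- cumsum(w * v); cq <- cumsum(w * v^2)
  seg_cost <- function(i, j) { # cost of v[i..j]
    W <- cw[j] - if (i > 1) cw[i - 1] else 0
    S <- cs[j] - if (i > 1) cs[i - 1] else 0
    Q <- cq[j] - if (i > 1) cq[i - 1] else 0
    Q - S^2 / W
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- seg_cost(1, j)
  if (k > 1) for (g in 2:k) for (j in g:n) {
    for (i in g:j) {
      c_ <- cost[g - 1, i - 1] + seg_cost(i, j)
      if (c_ < cost[g, j]) { cost[g, j] <- c_; back[g, j] <- i }
    }
  }
  groups <- integer(n)
  j <- n
  for (g in k:1) {
    i <- if (g == 1) 1L else back[g, j]
    groups[i:j] <- g
    j <- i - 1L
  }
  groups
}

#' Randomly partition a cohort into derivation and validation sets
#'
#' @param data Data frame to partition.
#' @param prop Proportion assigned to the derivation set (default 0.7).
#' @param seed Integer seed making the partition reproducible.
#' @return List with elements `derivation` and `validation`.
#' @export
partition_cohort <- function(data, prop = 0.7, seed = 1L) {
  stopifnot(prop > 0, prop < 1)
  n <- nrow(data)
  idx <- .with_seed(seed, sample.int(n, size = round(prop * n)))
  list(derivation = data[idx, , drop = FALSE],
       validation = data[-idx, , drop = FALSE])
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
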