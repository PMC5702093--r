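#' Fit a personal-support need-classification tree
#'
#' The package's central fitting function: recursive partitioning of weekly
#' personal-support hours by assessment variables using the variance-reduction
#' (F-test) criterion with Bonferroni-adjusted significance gating, followed
#' optionally by collapsing terminal nodes into `groups` ordered need groups.
#'
#' @param formula Model formula, e.g. `weekly_hours ~ adl_short + cps +
#'   iadl_difficulty`; `.` expands to all other columns.
#' @param data Data frame holding the target and candidate split variables.
#' @param control Growth parameters from [psa_control()].
#' @param groups Optional number of ordered groups to collapse the terminal
#'   nodes into (e.g. 6); `NULL` leaves terminals ungrouped.
#' @return An object of class `psa_tree` with components `tree`
#'   (`psa_treespec`), `leaf_stats`, `fitted`, `y`, `control`, `groups`,
#'   `call`.
#' @examples
#' set.seed(7)
#' d <- data.frame(adl = sample(0:6, 400, TRUE))
#' d$hours <- 2 + 3 * (d$adl >= 3) + rnorm(400, sd = 0.5)
#' fit <- psa_tree(hours ~ adl, d, control = psa_control(min_leaf = 30))
#' summary(fit)
#' @export
psa_tree <- function(formula, data, control = psa_control(), groups = NULL) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- mf[, -1, drop = FALSE]
  if (!is.numeric(y)) stop("target must be numeric", call. = FALSE)
  if (anyNA(y)) stop("target contains missing values", call. = FALSE)

  tree <- grow_tree(X, y, control)
  if (!is.null(groups)) tree <- collapse_leaves(tree, k = groups)

  leaf_id <- .route(X, tree)
  leaf_ids <- names(tree$nodes)[vapply(tree$nodes, function(n) n$type == "leaf", logical(1))]
  leaf_stats <- data.frame(
    node_id = leaf_ids,
    n = vapply(tree$nodes[leaf_ids], `[[`, numeric(1), "n"),
    mean = vapply(tree$nodes[leaf_ids], `[[`, numeric(1), "mean"),
    group = vapply(tree$nodes[leaf_ids], function(n) n$group %||% NA_character_, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  leaf_stats <- leaf_stats[order(leaf_stats$mean), , drop = FALSE]

  fitted <- stats::setNames(leaf_stats$mean, leaf_stats$node_id)[leaf_id]
  structure(list(tree = tree, leaf_stats = leaf_stats,
                 fitted = unname(fitted), y = y, leaf = unname(leaf_id),
                 control = control, groups = groups,
                 terms = stats::terms(mf), call = match.call()),
            class = "psa_tree")
}

#' @export
print.psa_tree <- function(x, ...) {
  cat("Variance-reduction need-classification tree\n")
  cat("  call: "); print(x$call)
  cat("  terminal nodes:", nrow(x$leaf_stats),
      if (!is.null(x$groups)) paste0("(collapsed into ", x$groups, " groups)"), "\n")
  cat("  n =", length(x$y), ", explained variance =",
      round(explained_variance(.leaf_or_group(x), x$y), 4), "\n")
  invisible(x)
}

.leaf_or_group <- function(x) {
  leaf_id <- .route_fit(x)
  if (!is.null(x$groups)) {
    vapply(leaf_id, function(id) x$tree$nodes[[id]]$group, character(1))
  } else leaf_id
}

# terminal node per training row, stored at fit time
.route_fit <- function(x) x$leaf

#' @export
summary.psa_tree <- function(object, ...) {
  leaf_group <- .leaf_or_group(object)
  out <- list(leaf_stats = object$leaf_stats,
              n = length(object$y),
              explained_variance = explained_variance(leaf_group, object$y),
              model_cv = model_cv(leaf_group, object$y),
              control = object$control)
  class(out) <- "summary.psa_tree"
  out
}

#' @export
print.summary.psa_tree <- function(x, ...) {
  cat("Need-classification tree: n =", x$n, "\n")
  cat("Explained variance:", round(x$explained_variance, 4),
      "  CV:", round(x$model_cv, 1), "%\n")
  cat("Terminal nodes (ordered by mean target):\n")
  print(x$leaf_stats, row.names = FALSE)
  invisible(x)
}

#' @export
coef.psa_tree <- function(object, ...) {
  ls <- object$leaf_stats
  if (!is.null(object$groups)) {
    num <- tapply(ls$mean * ls$n, ls$group, sum)
    den <- tapply(ls$n, ls$group, sum)
    gm <- num / den
    gm[order(as.integer(names(gm)))]
  } else stats::setNames(ls$mean, ls$node_id)
}

#' Predict from a fitted need-classification tree
#'
#' @param object A `psa_tree`.
#' @param newdata Data frame with the split variables; defaults to refitting
#'   values on the training data.
#' @param type `"mean"` (leaf mean hours), `"leaf"` (terminal node id) or
#'   `"group"` (collapsed group label; requires a collapsed tree).
#' @param ... Unused.
#' @export
predict.psa_tree <- function(object, newdata = NULL, type = c("mean", "leaf", "group"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "mean") return(object$fitted)
    leaf <- .route_fit(object)
  } else {
    leaf <- .route(as.data.frame(newdata), object$tree)
  }
  switch(type,
    leaf = unname(leaf),
    mean = unname(stats::setNames(object$leaf_stats$mean, object$leaf_stats$node_id)[leaf]),
    group = {
      if (is.null(object$groups)) stop("tree has no collapsed groups", call. = FALSE)
      unname(vapply(leaf, function(id) object$tree$nodes[[id]]$group, character(1)))
    })
}

#' @export
residuals.psa_tree <- function(object, ...) object$y - object$fitted

#' @export
fitted.psa_tree <- function(object, ...) object$fitted

#' Plot a fitted tree
#'
#' Draws the tree top-down with split rules on the edges and leaf means at
#' the terminals, using base graphics.
#'
#' @param x A `psa_tree` or `psa_treespec`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psa_tree <- function(x, ...) plot(x$tree, ...)

#' @export
plot.psa_treespec <- function(x, ...) {
  # compute leaf x-positions by in-order traversal, depth as y
  pos <- new.env()
  leaf_x <- 0
  layout <- function(id, depth) {
    node <- x$nodes[[id]]
    if (node$type == "leaf") {
      leaf_x <<- leaf_x + 1
      assign(id, c(leaf_x, depth), envir = pos)
    } else {
      for (ch in node$children) layout(ch, depth + 1)
      xs <- vapply(node$children, function(ch) get(ch, envir = pos)[1], numeric(1))
      assign(id, c(mean(xs), depth), envir = pos)
    }
  }
  layout(x$root, 1)
  coords <- t(vapply(names(x$nodes), function(id) get(id, envir = pos), numeric(2)))
  graphics::plot(coords[, 1], -coords[, 2], type = "n", axes = FALSE,
                 xlab = "", ylab = "", ...)
  for (id in names(x$nodes)) {
    node <- x$nodes[[id]]
    if (node$type == "split") {
      p <- get(id, envir = pos)
      for (ch in node$children) {
        q <- get(ch, envir = pos)
        graphics::segments(p[1], -p[2], q[1], -q[2], col = "grey50")
      }
      graphics::text(p[1], -p[2], paste0(node$variable, " < ", paste(node$cuts, collapse = ",")),
                     cex = 0.7)
    } else {
      p <- get(id, envir = pos)
      lab <- if (!is.null(node$group)) node$group else
        if (!is.null(node$mean)) sprintf("%.1f", node$mean) else id
      graphics::text(p[1], -p[2], lab, cex = 0.7, font = 2)
    }
  }
  invisible(x)
}
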