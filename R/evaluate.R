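#' Per-group summary statistics of weekly hours
#'
#' One row per group: size, share of cohort, mean, SD, median, quartiles and
#' the coefficient of variation (SD/mean). Quantiles use linear interpolation
#' of the empirical CDF (R's type 7), fixed so that bands are reproducible.
#'
#' @param groups Group label per observation (character or factor).
#' @param hours Numeric weekly hours, same length.
#' @return Data frame with columns `group`, `n`, `percent`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `cv`; ordered by group label. `cv` is `NA` when
#'   the group mean is 0.
#' @export
group_stats <- function(groups, hours) {
  stopifnot(length(groups) == length(hours))
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  out <- do.call(rbind, lapply(lev, function(g) {
    h <- hours[groups == g]
    q <- stats::quantile(h, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    m <- mean(h); s <- if (length(h) > 1) stats::sd(h) else 0
    data.frame(group = g, n = length(h),
               percent = 100 * length(h) / length(hours),
               mean = m, sd = s, median = q[2], q1 = q[1], q3 = q[3],
               cv = if (m > 0) s / m else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Explained variance of a grouping
#'
#' Proportion of the variability in hours explained by predicting every
#' member with its group mean: `1 - SSE/SST`, identical to the R-squared of
#' regressing hours on group indicators.
#'
#' @param groups Group label per observation.
#' @param hours Numeric target vector.
#' @return Proportion in \[0, 1\]; defined as 0 (with a warning) when the
#'   total sum of squares is 0.
#' @export
explained_variance <- function(groups, hours) {
  stopifnot(length(groups) == length(hours))
  grand <- mean(hours)
  sst <- sum((hours - grand)^2)
  if (sst == 0) { warning("zero total variance; explained variance defined as 0"); return(0) }
  mu <- tapply(hours, as.character(groups), mean)
  sse <- sum((hours - mu[as.character(groups)])^2)
  1 - sse / sst
}

#' Model coefficient of variation
#'
#' Relative closeness of the group-mean predictions to the actual hours:
#' 100 times the root-mean-square within-group residual divided by the grand
#' mean. This definition is a documented reconstruction consistent with
#' case-mix conventions.
#'
#' @inheritParams explained_variance
#' @return Percent (>= 0).
#' @export
model_cv <- function(groups, hours) {
  grand <- mean(hours)
  if (grand <= 0) stop("grand mean must be positive for the coefficient of variation", call. = FALSE)
  mu <- tapply(hours, as.character(groups), mean)
  rmse <- sqrt(mean((hours - mu[as.character(groups)])^2))
  100 * rmse / grand
}

#' Ratio of the highest to the lowest group mean
#'
#' @param stats A data frame from [group_stats()] (uses its `mean` column),
#'   or a numeric vector of group means.
#' @return `max(mean) / min(mean)`; `Inf` with a warning when the lowest
#'   mean is 0.
#' @export
group_ratio <- function(stats) {
  means <- if (is.data.frame(stats)) stats$mean else as.numeric(stats)
  lo <- min(means); hi <- max(means)
  if (lo <= 0) { warning("lowest group mean is not positive; ratio is infinite"); return(Inf) }
  hi / lo
}

#' Model fit within strata
#'
#' Computes explained variance, coefficient of variation and the group-mean
#' ratio separately within each level of a stratum variable (e.g. region or
#' assessment year), plus a min-max summary — the consistency check used to
#' validate a classification across regions and over time.
#'
#' @param groups,hours As in [explained_variance()].
#' @param strata Stratum label per observation.
#' @return Data frame with one row per stratum (`stratum`, `n`,
#'   `explained_variance`, `cv`, `group_ratio`); attribute `"range"` holds
#'   the min and max of each metric. Strata with fewer than 2 distinct
#'   groups are skipped with a warning.
#' @export
stratified_fit <- function(groups, hours, strata) {
  stopifnot(length(groups) == length(hours), length(hours) == length(strata))
  lev <- sort(unique(as.character(strata)))
  rows <- list()
  for (s in lev) {
    sel <- as.character(strata) == s
    if (length(unique(as.character(groups[sel]))) < 2) {
      warning("stratum '", s, "' has fewer than 2 groups; skipped")
      next
    }
    gs <- group_stats(groups[sel], hours[sel])
    rows[[s]] <- data.frame(stratum = s, n = sum(sel),
                            explained_variance = explained_variance(groups[sel], hours[sel]),
                            cv = model_cv(groups[sel], hours[sel]),
                            group_ratio = group_ratio(gs),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "range") <- if (!is.null(out)) apply(out[, c("explained_variance", "cv", "group_ratio")], 2, range)
  out
}
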