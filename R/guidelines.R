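#' Percentile-based allocation guideline bands
#'
#' For each need group, retrieves the 20th, 35th, 50th, 65th and 80th
#' percentiles of weekly hours. The median anchors the band; allocations are
#' expected to fall most frequently between the 35th and 65th percentile,
#' occasionally between the 20th/80th and the inner band, and only in
#' exceptional cases beyond the 20th-80th range. Apply
#' [apply_guideline_filters()] first. A narrower inner band (e.g. 45th-55th)
#' can be requested via `inner`.
#'
#' @param groups Group label per observation.
#' @param hours Weekly billed hours per observation.
#' @param inner Inner (typical) band percentiles, default `c(0.35, 0.65)`.
#' @param outer Outer (occasional) band percentiles, default `c(0.20, 0.80)`.
#' @param min_n Bands for groups with fewer observations are suppressed with
#'   a warning (default 30).
#' @return Data frame with columns `group`, `p_lo_outer`, `p_lo_inner`,
#'   `p50`, `p_hi_inner`, `p_hi_outer`, `n` plus conventional aliases
#'   `p20`, `p35`, `p65`, `p80` when the default percentiles are used.
#' @export
build_guidelines <- function(groups, hours, inner = c(0.35, 0.65),
                             outer = c(0.20, 0.80), min_n = 30) {
  stopifnot(length(groups) == length(hours),
            inner[1] < inner[2], outer[1] < outer[2],
            outer[1] <= inner[1], inner[2] <= outer[2])
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  rows <- list()
  for (g in lev) {
    h <- hours[groups == g]
    if (length(h) < min_n) {
      warning("group '", g, "' has n = ", length(h), " < ", min_n, "; band suppressed")
      next
    }
    q <- stats::quantile(h, c(outer[1], inner[1], 0.5, inner[2], outer[2]),
                         type = 7, names = FALSE)
    rows[[g]] <- data.frame(group = g, p_lo_outer = q[1], p_lo_inner = q[2],
                            p50 = q[3], p_hi_inner = q[4], p_hi_outer = q[5],
                            n = length(h), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (identical(inner, c(0.35, 0.65)) && identical(outer, c(0.20, 0.80)) && !is.null(out)) {
    out$p20 <- out$p_lo_outer; out$p35 <- out$p_lo_inner
    out$p65 <- out$p_hi_inner; out$p80 <- out$p_hi_outer
  }
  out
}

#' Zone of a proposed allocation within a group's guideline band
#'
#' Partitions the non-negative hours line exactly: `typical` within the inner
#' band (inclusive at both ends), `occasional` within the outer band but
#' outside the inner, `exceptional` beyond the outer band. Boundaries are
#' inclusive toward the centre, so the three zones neither overlap nor leave
#' gaps.
#'
#' @param group Group label(s) of the patient(s).
#' @param proposed_hours Proposed weekly hours, same length (or scalar).
#' @param bands Data frame from [build_guidelines()].
#' @return Character vector in `{"typical", "occasional", "exceptional"}`.
#' @export
allocation_zone <- function(group, proposed_hours, bands) {
  group <- as.character(group)
  idx <- match(group, bands$group)
  if (anyNA(idx)) stop("no guideline band for group(s): ",
                       paste(unique(group[is.na(idx)]), collapse = ", "), call. = FALSE)
  lo_o <- bands$p_lo_outer[idx]; lo_i <- bands$p_lo_inner[idx]
  hi_i <- bands$p_hi_inner[idx]; hi_o <- bands$p_hi_outer[idx]
  h <- proposed_hours
  ifelse(h >= lo_i & h <= hi_i, "typical",
         ifelse(h >= lo_o & h <= hi_o, "occasional", "exceptional"))
}

#' Statutory cap audit of allocated hours
#'
#' Ontario's statutory ceiling: up to 120 hours of personal support in the
#' first 30-day period of service and up to 90 hours in any subsequent 30-day
#' period. Totals at the ceiling pass ("up to" is inclusive); totals above it
#' are flagged unless an exemption applies (long-term-care waitlist, end of
#' life, or extraordinary circumstances), in which case the period passes but
#' the exemption is logged.
#'
#' @param allocations Data frame with columns `period` (1-based 30-day period
#'   index), `hours` (total hours in the period) and optionally `exemption`
#'   (`NA`/"" = none, otherwise a reason string).
#' @return The input with added columns `limit`, `over_limit`, `flagged`
#'   (over the limit and not exempt) and `exemption_logged`.
#' @export
statutory_check <- function(allocations) {
  stopifnot(all(c("period", "hours") %in% names(allocations)))
  if (any(allocations$hours < 0)) stop("negative allocated hours", call. = FALSE)
  if (any(allocations$period < 1)) stop("periods are indexed from 1", call. = FALSE)
  ex <- allocations$exemption %||% rep(NA_character_, nrow(allocations))
  has_ex <- !is.na(ex) & nzchar(as.character(ex))
  out <- allocations
  out$limit <- ifelse(out$period == 1, 120, 90)
  out$over_limit <- out$hours > out$limit
  out$flagged <- out$over_limit & !has_ex
  out$exemption_logged <- out$over_limit & has_ex
  out
}
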