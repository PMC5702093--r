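#' Weekly billed personal-support hours
#'
#' Computes the primary dependent variable from a billed-services log: for
#' each person, all services typed `personal_support` with
#' `assessment_date < service_date <= assessment_date + 84 days` (a half-open
#' 12-week window) are retained; the total hours are divided by the service
#' span (days between first and last visit, floored at 1 so a single visit is
#' defined) and multiplied by 7.
#'
#' @param billing Data frame with columns `person_id`, `service_date`,
#'   `service_type`, `hours`.
#' @param assessments Data frame with columns `person_id`,
#'   `assessment_date`.
#' @return Data frame, one row per assessment row, with columns `person_id`,
#'   `weekly_billed_hours`, `n_visits`, `service_days_span` (0 when no
#'   qualifying visits), `single_visit_flag` (span floored at 1).
#' @examples
#' b <- data.frame(person_id = "P1",
#'                 service_date = as.Date("2013-01-10") + c(1, 29),
#'                 service_type = "personal_support", hours = c(6, 6))
#' a <- data.frame(person_id = "P1", assessment_date = as.Date("2013-01-10"))
#' weekly_billed_hours(b, a)$weekly_billed_hours  # 12 h over 28 days -> 3
#' @export
weekly_billed_hours <- function(billing, assessments) {
  stopifnot(all(c("person_id", "service_date", "service_type", "hours") %in% names(billing)),
            all(c("person_id", "assessment_date") %in% names(assessments)))
  if (any(billing$hours < 0)) stop("negative service hours", call. = FALSE)
  billing$service_date <- as.Date(billing$service_date)
  assessments$assessment_date <- as.Date(assessments$assessment_date)

  ps <- billing[billing$service_type == "personal_support", , drop = FALSE]
  a_date <- stats::setNames(assessments$assessment_date, assessments$person_id)
  ps <- ps[ps$person_id %in% names(a_date), , drop = FALSE]
  ad <- a_date[ps$person_id]
  in_window <- ps$service_date > ad & ps$service_date <= ad + 84
  ps <- ps[in_window, , drop = FALSE]

  tot <- tapply(ps$hours, ps$person_id, sum)
  first <- tapply(as.numeric(ps$service_date), ps$person_id, min)
  last <- tapply(as.numeric(ps$service_date), ps$person_id, max)
  nv <- tapply(ps$hours, ps$person_id, length)

  out <- data.frame(person_id = assessments$person_id, stringsAsFactors = FALSE)
  idx <- match(out$person_id, names(tot))
  span_raw <- ifelse(is.na(idx), 0, last[idx] - first[idx])
  out$n_visits <- ifelse(is.na(idx), 0L, as.integer(nv[idx]))
  out$service_days_span <- as.integer(span_raw)
  span <- pmax(span_raw, 1)
  out$weekly_billed_hours <- ifelse(is.na(idx), 0, as.numeric(tot[idx]) / span * 7)
  out$single_visit_flag <- out$n_visits >= 1 & span_raw == 0
  out
}

#' Weekly estimated personal-support hours
#'
#' Secondary dependent variable from the assessment itself: minutes of home
#' health aide plus homemaking services received in the 7-day lookback,
#' converted to hours per week.
#'
#' @param records Assessment data frame with `estimated_aide_minutes` and
#'   `estimated_homemaking_minutes`.
#' @return Numeric vector of hours per week.
#' @export
weekly_estimated_hours <- function(records) {
  (records$estimated_aide_minutes + records$estimated_homemaking_minutes) / 60
}

#' Apply the derivation-cohort exclusion rules
#'
#' Sequentially excludes (first-match accounting): (1) assessments completed
#' in hospital; (2) patients receiving case-management or long-term-care
#' placement services only; (3) patients with under three weeks of active
#' service (span < 21 days, including those with no service at all); and then
#' (4) patients above the 99th percentile of weekly billed hours, the
#' percentile being computed on the cohort remaining after the structural
#' rules so that it reflects the analytic population.
#'
#' @param cohort Data frame carrying `weekly_billed_hours`,
#'   `service_days_span` and the flag columns `assessed_in_hospital`,
#'   `case_mgmt_or_placement_only` (0/1).
#' @param p99_threshold Optional fixed utilisation ceiling. By default the
#'   99th percentile is estimated from the cohort passing the structural
#'   rules and stored as attribute `"p99_threshold"`; pass that value back in
#'   to re-apply the identical filter set (making the operation idempotent).
#' @return The retained rows; attribute `"ledger"` is a named count of
#'   exclusions per rule plus `retained`; attribute `"p99_threshold"` the
#'   ceiling used.
#' @export
apply_derivation_filters <- function(cohort, p99_threshold = NULL) {
  need <- c("weekly_billed_hours", "service_days_span",
            "assessed_in_hospital", "case_mgmt_or_placement_only")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing filter column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n0 <- nrow(cohort)
  excluded <- rep(NA_character_, n0)
  mark <- function(rule, cond) {
    hit <- is.na(excluded) & cond
    excluded[hit] <<- rule
  }
  mark("hospital", cohort$assessed_in_hospital == 1)
  mark("case_mgmt_or_placement_only", cohort$case_mgmt_or_placement_only == 1)
  mark("under_3_weeks_service", cohort$service_days_span < 21)
  remaining <- is.na(excluded)
  p99 <- p99_threshold
  if (is.null(p99) && any(remaining))
    p99 <- stats::quantile(cohort$weekly_billed_hours[remaining], 0.99, type = 7, names = FALSE)
  if (!is.null(p99)) mark("above_99th_percentile", cohort$weekly_billed_hours > p99)
  out <- cohort[is.na(excluded), , drop = FALSE]
  attr(out, "p99_threshold") <- p99
  ledger <- c(table(factor(excluded, levels = c("hospital", "case_mgmt_or_placement_only",
                                                "under_3_weeks_service", "above_99th_percentile"))),
              retained = nrow(out))
  attr(out, "ledger") <- ledger
  out
}

#' Apply the guideline-cohort exclusion rules
#'
#' For building allocation guidelines (not derivation): excludes (1) patients
#' residing in a retirement home, supportive housing or assisted living; (2)
#' patients on a waitlist or on hold who received no personal support in the
#' 12-week window; and (3) patients in Groups 3 to 6 who received no personal
#' support. There is no top-percentile exclusion in this path: the highest
#' utilisers stay in, reflecting real-world applicability.
#'
#' @param cohort Data frame carrying `setting`, `on_waitlist_or_hold`,
#'   `weekly_billed_hours` and the classification column `top_level`
#'   (NA allowed; such rows cannot be assessed by rule 3 and are reported).
#' @return Retained rows with attribute `"ledger"` (counts per rule,
#'   `unclassified` rows rule 3 could not assess, and `retained`).
#' @export
apply_guideline_filters <- function(cohort) {
  need <- c("setting", "on_waitlist_or_hold", "weekly_billed_hours", "top_level")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing filter column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  congregate <- c("retirement_home", "supportive_housing", "assisted_living")
  excluded <- rep(NA_character_, nrow(cohort))
  mark <- function(rule, cond) {
    cond[is.na(cond)] <- FALSE
    hit <- is.na(excluded) & cond
    excluded[hit] <<- rule
  }
  mark("congregate_setting", cohort$setting %in% congregate)
  mark("waitlist_no_service", cohort$on_waitlist_or_hold == 1 & cohort$weekly_billed_hours == 0)
  mark("group3plus_no_service", cohort$top_level >= 3 & cohort$weekly_billed_hours == 0)
  out <- cohort[is.na(excluded), , drop = FALSE]
  ledger <- c(table(factor(excluded, levels = c("congregate_setting", "waitlist_no_service",
                                                "group3plus_no_service"))),
              unclassified = sum(is.na(cohort$top_level)),
              retained = nrow(out))
  attr(out, "ledger") <- ledger
  out
}
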