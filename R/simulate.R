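#' Calibrate a lognormal to a printed median and quartiles
#'
#' Sets `meanlog = log(median)` so the distribution's median matches exactly,
#' and chooses `sdlog` by least squares against both printed quartiles on the
#' log scale. If the implied quartiles miss the targets by more than 10%
#' relative error a warning is raised (the printed median and quartiles need
#' not be jointly attainable by a two-parameter family).
#'
#' @param median,q1,q3 Target median and quartiles, `0 < q1 <= median <= q3`,
#'   `q1 < q3`.
#' @return List with `meanlog`, `sdlog` and the `implied` quartiles.
#' @export
fit_quantile_lognormal <- function(median, q1, q3) {
  if (!(q1 > 0 && q1 <= median && median <= q3 && q1 < q3))
    stop("need 0 < q1 <= median <= q3 with q1 < q3 (use the zero-inflated mode for mass at zero)",
         call. = FALSE)
  mu <- log(median)
  z <- stats::qnorm(c(0.25, 0.75))
  d <- c(log(q1) - mu, log(q3) - mu)
  sigma <- sum(z * d) / sum(z^2)
  implied <- exp(mu + z * sigma)
  rel <- abs(implied - c(q1, q3)) / c(q1, q3)
  if (any(rel > 0.10))
    warning(sprintf("fitted lognormal reproduces quartiles within %.1f%%/%.1f%% (targets %.2f/%.2f, implied %.2f/%.2f)",
                    100 * rel[1], 100 * rel[2], q1, q3, implied[1], implied[2]))
  list(meanlog = mu, sdlog = sigma, implied = implied)
}

#' Calibrate a gamma to a printed mean and SD
#'
#' Moment matching: `shape = (mean/sd)^2`, `scale = sd^2/mean`; the implied
#' mean and SD equal the inputs exactly.
#'
#' @param mean,sd Positive target mean and standard deviation.
#' @return List with `shape` and `scale`.
#' @export
fit_moment_gamma <- function(mean, sd) {
  if (!(mean > 0 && sd > 0)) stop("mean and sd must be positive", call. = FALSE)
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Default group calibration of the synthetic cohort
#'
#' One entry per display group with its target share of the cohort and its
#' weekly-hours model. Shares and hour parameters are the published per-group
#' statistics of billed personal-support hours: shares 6.4 / 45.5 / 28.2 /
#' 7.6 / 6.6 / 5.7% for Groups 1-6 (Group 1 split evenly over 1A/1B/1C);
#' Group 1 hours are zero-inflated (80% zeros and a small lognormal positive
#' part, consistent with an all-zero interquartile range and mean 0.4);
#' Group 3 uses gamma moment calibration (mean 4.8, SD 4.3); the remaining
#' groups use lognormal quantile calibration to their printed median and
#' quartiles.
#'
#' @return Named list of calibrations, one per display group; each has
#'   `share` and `hours_model` (with a `mode` field).
#' @export
psa_calibration <- function() {
  ql <- function(median, q1, q3) c(list(mode = "quantile_lognormal"),
                                   suppressWarnings(fit_quantile_lognormal(median, q1, q3)))
  g1 <- list(mode = "zero_inflated", p_zero = 0.8, meanlog = log(1.5), sdlog = 0.8)
  list(
    `1A` = list(share = 0.064 / 3, hours_model = g1),
    `1B` = list(share = 0.064 / 3, hours_model = g1),
    `1C` = list(share = 0.064 / 3, hours_model = g1),
    `2` = list(share = 0.455, hours_model = ql(1.7, 0.9, 2.8)),
    `3` = list(share = 0.282, hours_model = c(list(mode = "moment_gamma"), fit_moment_gamma(4.8, 4.3))),
    `4` = list(share = 0.076, hours_model = ql(5.7, 2.7, 10.2)),
    `5` = list(share = 0.066, hours_model = ql(7.0, 3.5, 13.1)),
    `6` = list(share = 0.057, hours_model = ql(12.0, 6.3, 14.8)))
}

#' Draw weekly hours from a calibrated group model
#'
#' @param model An `hours_model` entry from [psa_calibration()].
#' @param n Number of draws.
#' @return Numeric vector of non-negative weekly hours.
#' @export
sample_group_hours <- function(model, n) {
  switch(model$mode,
    quantile_lognormal = stats::rlnorm(n, model$meanlog, model$sdlog),
    moment_gamma = stats::rgamma(n, shape = model$shape, scale = model$scale),
    zero_inflated = {
      pos <- stats::rlnorm(n, model$meanlog, model$sdlog)
      ifelse(stats::runif(n) < model$p_zero, 0, pos)
    },
    stop("unknown hours model mode: ", model$mode, call. = FALSE))
}

# --- assessment-record proposals, one per display group -----------------

# helpers drawing n values from a discrete set (uniform unless probs given)
.draw <- function(n, values, prob = NULL) sample(values, n, replace = TRUE, prob = prob)

# distribute each total (0..6) across three 0-2 items uniformly at random
.split_iadl <- function(totals) {
  out <- matrix(0L, length(totals), 3)
  for (i in seq_along(totals)) {
    x <- c(0L, 0L, 0L)
    s <- totals[i]
    while (s > 0L) {
      j <- which(x < 2L)
      pick <- if (length(j) == 1L) j else sample(j, 1L)
      x[pick] <- x[pick] + 1L
      s <- s - 1L
    }
    out[i, ] <- x
  }
  out
}

.base_records <- function(n, start_id = 1L) {
  rec <- psa_example_record()[rep(1, n), ]
  rec$person_id <- sprintf("S%06d", seq.int(start_id, length.out = n))
  rec$assessment_date <- as.Date("2013-01-01") + sample(0:330, n, replace = TRUE)
  rec$age <- pmin(pmax(round(stats::rnorm(n, 78, 14.2)), 18), 110)
  rec$sex <- .draw(n, c("F", "M"), c(0.649, 0.351))
  rec$living_alone <- .draw(n, 0:1, c(0.669, 0.331))
  rec$setting <- .draw(n, c("community", "retirement_home", "supportive_housing", "assisted_living"),
                       c(0.91, 0.04, 0.03, 0.02))
  rec$on_waitlist_or_hold <- .draw(n, 0:1, c(0.95, 0.05))
  rownames(rec) <- NULL
  rec
}

.propose_for_group <- function(display, n, start_id = 1L) {
  rec <- .base_records(n, start_id)
  low_adl_codes <- function(n) .draw(n, 0:1)           # recode 0
  if (display %in% c("1A", "1B", "1C")) {
    # Self-Reliance Index intact; IADL difficulty drives the sublevel
    rec$decision_making <- 0
    for (it in c("bathing", "personal_hygiene", "dressing_lower", "walking_indoors",
                 "walking_outdoors", "locomotion", "toilet_use", "eating",
                 "dressing_upper", "bed_mobility")) rec[[it]] <- low_adl_codes(n)
    tot <- switch(display, `1A` = .draw(n, 0:1), `1B` = .draw(n, 2:4), `1C` = .draw(n, 5:6))
    ii <- .split_iadl(tot)
    rec$meal_preparation <- ii[, 1]; rec$ordinary_housework <- ii[, 2]; rec$phone_use <- ii[, 3]
    rec$bladder_incontinence <- .draw(n, 0:2, c(0.5, 0.3, 0.2))
  } else if (display == "2") {
    rec$bathing <- .draw(n, 2:3)                       # triggers the index, outside ADL Short
    rec$decision_making <- 0
    for (it in c("personal_hygiene", "toilet_use", "locomotion", "eating"))
      rec[[it]] <- low_adl_codes(n)
    which2 <- stats::runif(n) < 0.4                    # some rows carry one supervised item
    rec$personal_hygiene[which2] <- 2
    rec$dressing_upper <- ifelse(stats::runif(n) < 0.7, .draw(n, 0:1), .draw(n, 2:3))
    ii <- .split_iadl(.draw(n, 0:4))
    rec$meal_preparation <- ii[, 1]; rec$ordinary_housework <- ii[, 2]; rec$phone_use <- ii[, 3]
    rec$bladder_incontinence <- .draw(n, 0:3, c(0.4, 0.2, 0.25, 0.15))
  } else if (display == "3") {
    # mixture of the low-ADL decision-making path and the clean moderate path
    low_path <- stats::runif(n) < 0.3
    rec$bathing <- .draw(n, 2:3)
    rec$decision_making <- ifelse(low_path, 1, .draw(n, 0:1))
    rec$personal_hygiene <- ifelse(low_path, low_adl_codes(n), .draw(n, 3:4))
    rec$toilet_use <- ifelse(low_path, low_adl_codes(n), .draw(n, 2:3))
    rec$locomotion <- ifelse(low_path, low_adl_codes(n), .draw(n, 0:3))
    rec$eating <- ifelse(low_path, low_adl_codes(n), .draw(n, 0:2))
    rec$dressing_upper <- ifelse(low_path, .draw(n, 2:3), .draw(n, 0:2))
    rec$unstable_conditions <- 0
    rec$short_term_memory_ok <- 1
    rec$making_self_understood <- 0
    ii <- .split_iadl(.draw(n, 2:6))
    rec$meal_preparation <- ii[, 1]; rec$ordinary_housework <- ii[, 2]; rec$phone_use <- ii[, 3]
    rec$bladder_incontinence <- .draw(n, 0:3)
  } else if (display == "4") {
    # moderate ADL impairment with unstable health (4a) or cognitive impairment
    # without weekly bladder incontinence (4b)
    cog_path <- stats::runif(n) < 0.5
    rec$bathing <- .draw(n, 2:4)
    rec$personal_hygiene <- .draw(n, 3:4)
    rec$toilet_use <- .draw(n, 2:3)
    rec$locomotion <- .draw(n, 0:3)
    rec$eating <- .draw(n, 0:2)
    rec$decision_making <- ifelse(cog_path, 2, .draw(n, 0:1))
    rec$short_term_memory_ok <- ifelse(cog_path, 0, 1)
    rec$making_self_understood <- 0
    rec$unstable_conditions <- ifelse(cog_path, .draw(n, 0:1), 1)
    rec$bladder_incontinence <- ifelse(cog_path, .draw(n, 0:1), .draw(n, 0:3))
    ii <- .split_iadl(.draw(n, 3:6))
    rec$meal_preparation <- ii[, 1]; rec$ordinary_housework <- ii[, 2]; rec$phone_use <- ii[, 3]
  } else if (display == "5") {
    # moderate ADL + cognitive impairment + weekly bladder incontinence (5a),
    # or highest ADL impairment without bowel/communication triggers (5b)
    high_path <- stats::runif(n) < 0.5
    rec$bathing <- .draw(n, 3:5)
    rec$personal_hygiene <- ifelse(high_path, 6, .draw(n, 3:4))
    rec$toilet_use <- ifelse(high_path, .draw(n, 4:5), .draw(n, 2:3))
    rec$locomotion <- ifelse(high_path, .draw(n, 4:6), .draw(n, 0:3))
    rec$eating <- ifelse(high_path, 3, .draw(n, 0:2))
    rec$decision_making <- ifelse(high_path, .draw(n, 0:1), 2)
    rec$short_term_memory_ok <- ifelse(high_path, 1, 0)
    rec$making_self_understood <- ifelse(high_path, .draw(n, 0:1), .draw(n, 0:1))
    rec$bladder_incontinence <- ifelse(high_path, .draw(n, 0:5), .draw(n, 2:5))
    rec$bowel_incontinence <- ifelse(high_path, .draw(n, 0:1), .draw(n, 0:1))
    rec$caregiver_distress <- ifelse(high_path, 0, .draw(n, 0:1))
    ii <- .split_iadl(.draw(n, 4:6))
    rec$meal_preparation <- ii[, 1]; rec$ordinary_housework <- ii[, 2]; rec$phone_use <- ii[, 3]
  } else if (display == "6") {
    # highest ADL impairment with bowel incontinence or communication
    # difficulty, plus caregiver distress
    comm_path <- stats::runif(n) < 0.3
    rec$bathing <- .draw(n, 4:6)
    rec$personal_hygiene <- 6
    rec$toilet_use <- .draw(n, 4:6)
    rec$locomotion <- .draw(n, 4:6)
    rec$eating <- .draw(n, 3:6)
    rec$decision_making <- .draw(n, 1:4)
    rec$short_term_memory_ok <- .draw(n, 0:1)
    rec$making_self_understood <- ifelse(comm_path, .draw(n, 2:4), .draw(n, 0:4))
    rec$bowel_incontinence <- ifelse(comm_path, .draw(n, 0:1), .draw(n, 2:5))
    rec$bladder_incontinence <- .draw(n, 2:5)
    rec$caregiver_distress <- 1
    ii <- .split_iadl(.draw(n, 4:6))
    rec$meal_preparation <- ii[, 1]; rec$ordinary_housework <- ii[, 2]; rec$phone_use <- ii[, 3]
  } else stop("unknown display group: ", display, call. = FALSE)
  rec
}

#' Sample assessment records that classify into a requested group
#'
#' Draws records from a group-tailored proposal distribution over the item
#' space and keeps only those the tree classifies into the requested display
#' group (rejection sampling); the returned records round-trip through
#' [classify_cohort()] by construction.
#'
#' @param display Target display group ("1A".."6").
#' @param n Number of records.
#' @param tree Classification tree (`psa_treespec`).
#' @param start_id First numeric suffix for generated person ids.
#' @return Assessment data frame of `n` rows.
#' @export
sample_record_for_group <- function(display, n, tree = psa_reference_tree(), start_id = 1L) {
  out <- NULL
  need <- n
  for (iter in 1:50) {
    prop <- .propose_for_group(display, need, start_id + n - need)
    got <- classify_cohort(prop, tree)$display
    ok <- prop[got == display, , drop = FALSE]
    out <- rbind(out, ok)
    need <- n - nrow(out)
    if (need == 0L) break
  }
  if (need > 0L) stop("could not sample records for group ", display,
                      " (is the group reachable under this tree?)", call. = FALSE)
  out$person_id <- sprintf("S%06d", seq.int(start_id, length.out = n))
  rownames(out) <- NULL
  out
}

# --- billing decomposition ----------------------------------------------

# Choose a service span s (days, 21..83) and quarter-hour total k so that
# 7 * 0.25k / s is as close as possible to the weekly target; returns a
# data frame with s, k and the realised weekly hours.
.plan_billing <- function(weekly) {
  n <- length(weekly)
  best_err <- rep(Inf, n); best_s <- rep(83L, n); best_k <- rep(0L, n)
  pos <- weekly > 0
  for (s in 21:83) {
    k <- pmax(round(weekly * s / 1.75), 2)  # at least two visits: span is always realised
    real <- 1.75 * k / s
    err <- abs(real - weekly)
    better <- pos & err < best_err - 1e-12
    best_err[better] <- err[better]; best_s[better] <- s; best_k[better] <- k[better]
  }
  data.frame(s = best_s, k = ifelse(pos, best_k, 0L),
             realised = ifelse(pos, 1.75 * best_k / best_s, 0))
}

#' Decompose weekly hours into a billed-visit log
#'
#' Builds service records inside the 12-week post-assessment window whose
#' recomputed weekly billed hours reproduce the target: visits of 0.25-hour
#' granularity spread between a first visit the day after assessment and a
#' last visit fixing the chosen service span. Targets too small to support
#' two visits fall back to a single visit (flagged by the span guard in
#' [weekly_billed_hours()]).
#'
#' @param person_id,assessment_date,weekly_hours Equal-length vectors.
#' @return Billing data frame (`person_id`, `service_date`, `service_type`,
#'   `hours`).
#' @export
decompose_billing <- function(person_id, assessment_date, weekly_hours) {
  assessment_date <- as.Date(assessment_date)
  plan <- .plan_billing(weekly_hours)
  active <- which(plan$k >= 2L)
  per <- lapply(active, function(i) {
    k <- plan$k[i]; s <- plan$s[i]
    nv <- max(2L, min(as.integer(ceiling(k / 16)), k, 24L))
    offs <- unique(round(seq(1, 1 + s, length.out = nv)))
    nv_eff <- length(offs)
    base <- k %/% nv_eff; extra <- k %% nv_eff
    quarters <- rep(base, nv_eff) + c(rep(1L, extra), rep(0L, nv_eff - extra))
    list(offs = offs, quarters = quarters)
  })
  lens <- vapply(per, function(p) length(p$offs), integer(1))
  out <- data.frame(
    person_id = rep(person_id[active], lens),
    service_date = rep(assessment_date[active], lens) +
      unlist(lapply(per, `[[`, "offs")),
    service_type = "personal_support",
    hours = 0.25 * unlist(lapply(per, `[[`, "quarters")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic cohort
#'
#' Draws group memberships with the calibrated shares, samples assessment
#' records that classify into each drawn group, draws weekly hours from the
#' group's calibrated model, and decomposes the hours into a billed-service
#' log from which [weekly_billed_hours()] recovers them. Fully reproducible
#' under a fixed seed.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param calibration Group calibration list ([psa_calibration()]).
#' @param tree Classification tree.
#' @return List with data frames `assessments`, `billing` and `truth`
#'   (`person_id`, `display`, `top_level`, `weekly_hours` as drawn,
#'   `weekly_hours_realised` as recoverable from billing).
#' @export
generate_cohort <- function(n, seed = 1L, calibration = psa_calibration(),
                            tree = psa_reference_tree()) {
  stopifnot(n >= 1)
  shares <- vapply(calibration, `[[`, numeric(1), "share")
  stopifnot(abs(sum(shares) - 1) < 1e-6)
  .with_seed(seed, {
    display <- sample(names(calibration), n, replace = TRUE, prob = shares)
    counts <- table(factor(display, levels = names(calibration)))
    recs <- list(); truths <- list()
    next_id <- 1L
    for (g in names(calibration)) {
      ng <- as.integer(counts[[g]])
      if (ng == 0L) next
      r <- sample_record_for_group(g, ng, tree, start_id = next_id)
      h <- sample_group_hours(calibration[[g]]$hours_model, ng)
      recs[[g]] <- r
      truths[[g]] <- data.frame(person_id = r$person_id, display = g,
                                top_level = as.integer(substr(g, 1, 1)),
                                weekly_hours = h, stringsAsFactors = FALSE)
      next_id <- next_id + ng
    }
    assessments <- do.call(rbind, recs)
    truth <- do.call(rbind, truths)
    ord <- order(truth$person_id)
    assessments <- assessments[order(assessments$person_id), , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(assessments) <- rownames(truth) <- NULL
    # estimated (7-day lookback) minutes loosely track the billed hours,
    # rounded to the 10-minute assessment granularity
    rel <- stats::runif(nrow(truth), 0.8, 1.5)
    est_total <- round(truth$weekly_hours * 60 * rel / 10) * 10
    hm_share <- stats::runif(nrow(truth), 0, 0.4)
    assessments$estimated_homemaking_minutes <- round(est_total * hm_share / 10) * 10
    assessments$estimated_aide_minutes <- est_total - assessments$estimated_homemaking_minutes

    billing <- decompose_billing(truth$person_id, assessments$assessment_date,
                                 truth$weekly_hours)
    plan <- .plan_billing(truth$weekly_hours)
    truth$weekly_hours_realised <- plan$realised
    list(assessments = assessments, billing = billing, truth = truth)
  })
}
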