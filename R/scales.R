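#' interRAI-derived clinical scales
#'
#' Calculators for the five scale summaries feeding the Personal Support
#' Algorithm: the Self-Reliance Index, the 4-item ADL Short Scale (0-16), the
#' ADL Hierarchy (0-6), the Cognitive Performance Scale (0-6) and the IADL
#' Difficulty Scale (0-6). All calculators are vectorised over the rows of an
#' assessment data frame and are pure functions of the item codes.
#'
#' @name psa_scales
#' @param records Assessment data frame (see [parse_assessments()]); one or
#'   more rows.
NULL

.recode_adl <- function(x) {
  map <- .adl_recode_map()
  out <- unname(map[as.character(x)])
  bad <- is.na(out) & !is.na(x)   # NA items propagate; unknown codes are an error
  if (any(bad)) stop("invalid ADL self-performance code: ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' @describeIn psa_scales Self-Reliance Index: `TRUE` (impaired) when there is
#'   any difficulty making safe and reasonable decisions (`decision_making >=
#'   1`) or supervision/any physical help (code >= 2, with 8 counting as
#'   dependent) in bathing, personal hygiene, dressing lower body, walking
#'   indoors/outdoors or locomotion.
#' @export
self_reliance_index <- function(records) {
  adl_items <- c("bathing", "personal_hygiene", "dressing_lower",
                 "walking_indoors", "walking_outdoors", "locomotion")
  helped <- Reduce(`|`, lapply(adl_items, function(it) {
    x <- records[[it]]
    x >= 2  # codes 2..6 and 8: supervision or any physical help / did not occur
  }))
  unname(records$decision_making >= 1 | helped)
}

#' @describeIn psa_scales ADL Short Scale: sum over personal hygiene, toilet
#'   use, locomotion and eating of the bundled 0-6/8 to 0-4 dependence recode;
#'   range 0-16.
#' @export
adl_short <- function(records) {
  items <- c("personal_hygiene", "toilet_use", "locomotion", "eating")
  Reduce(`+`, lapply(items, function(it) .recode_adl(records[[it]])))
}

#' @describeIn psa_scales ADL Hierarchy: 0-6 hierarchical score over the same
#'   four items distinguishing early-loss (hygiene, locomotion) from late-loss
#'   (eating, toilet use) activities. 0 = independent, 6 = total dependence.
#' @export
adl_hierarchy <- function(records) {
  hy <- .recode_adl(records$personal_hygiene)
  tu <- .recode_adl(records$toilet_use)
  lo <- .recode_adl(records$locomotion)
  ea <- .recode_adl(records$eating)
  out <- integer(length(hy))
  out[which(hy >= 1 | tu >= 1 | lo >= 1 | ea >= 1)] <- 1L   # supervision-level help somewhere
  out[which(hy >= 2 | tu >= 2 | lo >= 2 | ea >= 2)] <- 2L   # limited assistance somewhere
  out[which(hy >= 3 | lo >= 3)] <- 3L                       # extensive help, early-loss
  out[which(ea == 3 | tu == 3)] <- 4L                       # extensive help, late-loss
  out[which(ea == 4 | tu == 4)] <- 5L                       # dependent in a late-loss ADL
  out[which(hy == 4 & tu == 4 & lo == 4 & ea == 4)] <- 6L   # total dependence
  out[is.na(hy) | is.na(tu) | is.na(lo) | is.na(ea)] <- NA_integer_
  out
}

#' @describeIn psa_scales Cognitive Performance Scale: 0-6 from daily decision
#'   making, short-term memory, making self understood and eating. Severely
#'   impaired decision making (code 4) maps to 5, or 6 with total dependence
#'   in eating; otherwise counts of impairment (decision >= 1, memory problem,
#'   understood >= 1) and severe impairment (decision >= 2, understood >= 2)
#'   grade levels 0-4.
#' @export
cps <- function(records) {
  dm <- records$decision_making
  mem_bad <- records$short_term_memory_ok == 0
  und <- records$making_self_understood
  eat_dep <- records$eating %in% c(6, 8)

  imp <- (dm >= 1) + mem_bad + (und >= 1)
  sev <- (dm >= 2) + (und >= 2)

  out <- integer(length(dm))
  out[which(imp == 1)] <- 1L
  out[which(imp >= 2)] <- 2L
  out[which(imp >= 2 & sev == 1)] <- 3L
  out[which(imp >= 2 & sev >= 2)] <- 4L
  out[which(dm == 4)] <- 5L
  out[which(dm == 4 & eat_dep)] <- 6L
  out[is.na(dm) | is.na(mem_bad) | is.na(und) | is.na(eat_dep)] <- NA_integer_
  out
}

#' @describeIn psa_scales IADL Difficulty Scale: sum of the 0-2 difficulty
#'   codes for meal preparation, ordinary housework and phone use; range 0-6.
#' @export
iadl_difficulty <- function(records) {
  records$meal_preparation + records$ordinary_housework + records$phone_use
}

#' Compute the full scale profile
#'
#' Applies all five scale calculators and returns them as columns; the result
#' is what the classifier consumes alongside the raw items.
#'
#' @param records Assessment data frame.
#' @return Data frame with columns `self_reliance_impaired` (0/1),
#'   `adl_short`, `adl_hierarchy`, `cps`, `iadl_difficulty`, one row per
#'   record.
#' @examples
#' scale_profile(psa_example_record(bathing = 2))
#' @export
scale_profile <- function(records) {
  data.frame(
    self_reliance_impaired = as.integer(self_reliance_index(records)),
    adl_short = adl_short(records),
    adl_hierarchy = adl_hierarchy(records),
    cps = cps(records),
    iadl_difficulty = iadl_difficulty(records))
}
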