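#' Read and validate assessment records
#'
#' Reads a CSV of assessment records (one row per assessment, columns named
#' exactly as in the data dictionary) and validates every item code against
#' the dictionary. Invalid rows are dropped from the returned table and
#' collected into a structured error report available through
#' [assessment_errors()].
#'
#' @param source Path to a CSV file, or a data frame already in memory.
#' @param dictionary Data dictionary as returned by [psa_dictionary()].
#' @return A data frame of valid assessment records with attribute
#'   `"errors"`: a data frame with columns `row`, `column`, `value`,
#'   `message` (zero rows when everything validated).
#' @examples
#' rec <- psa_example_record()
#' out <- parse_assessments(rec)
#' nrow(assessment_errors(out)) # 0
#' @export
parse_assessments <- function(source, dictionary = psa_dictionary()) {
  df <- if (is.character(source)) {
    # read everything as character: validation and typing are dictionary-driven
    # (and e.g. a sex column of "F"s must not become logical)
    utils::read.csv(source, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    as.data.frame(source, stringsAsFactors = FALSE)
  }

  required <- names(dictionary)[vapply(dictionary, function(d) isTRUE(d$required), logical(1))]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("assessment file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  errors <- list()
  bad <- rep(FALSE, nrow(df))
  for (col in names(dictionary)) {
    spec <- dictionary[[col]]
    x <- df[[col]]
    viol <- switch(spec$type,
      id      = !nzchar(as.character(x)) | is.na(x),
      date    = is.na(as.Date(as.character(x), format = "%Y-%m-%d")),
      code    = is.na(x) | !(suppressWarnings(as.numeric(x)) %in% spec$codes),
      numeric = {
        v <- suppressWarnings(as.numeric(x))
        is.na(v) | (!is.null(spec$min) & v < (spec$min %||% -Inf)) |
          (!is.null(spec$max) & v > (spec$max %||% Inf))
      },
      factor  = is.na(x) | !(as.character(x) %in% spec$levels),
      rep(FALSE, nrow(df)))
    if (any(viol)) {
      errors[[length(errors) + 1L]] <- data.frame(
        row = which(viol), column = col,
        value = as.character(x[viol]),
        message = paste0(col, " out of range"),
        stringsAsFactors = FALSE)
      bad <- bad | viol
    }
  }

  err_df <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), column = character(), value = character(),
               message = character(), stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    out$assessment_date <- as.Date(as.character(out$assessment_date))
    for (col in names(dictionary)) {
      if (dictionary[[col]]$type %in% c("code", "numeric")) out[[col]] <- as.numeric(out[[col]])
    }
  }
  attr(out, "errors") <- err_df[order(err_df$row), , drop = FALSE]
  class(out) <- c("psa_assessments", class(out))
  out
}

#' @rdname parse_assessments
#' @param x An object returned by [parse_assessments()].
#' @export
assessment_errors <- function(x) {
  attr(x, "errors") %||%
    data.frame(row = integer(), column = character(), value = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Write assessment records to CSV
#'
#' Writes records in the exact column layout expected by
#' [parse_assessments()], so that write-then-read round-trips.
#'
#' @param records Assessment data frame.
#' @param path Output CSV path.
#' @export
write_assessments <- function(records, path) {
  out <- as.data.frame(records)
  attr(out, "errors") <- NULL
  class(out) <- "data.frame"
  out$assessment_date <- format(as.Date(out$assessment_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A single fully-specified example assessment record
#'
#' Convenience constructor used in examples and tests: returns a one-row data
#' frame describing a fully independent community-dwelling person; individual
#' items can be overridden through `...`.
#'
#' @param ... Named item overrides, e.g. `bathing = 3`.
#' @return One-row data frame with every dictionary column populated.
#' @export
psa_example_record <- function(...) {
  rec <- data.frame(
    person_id = "P0001", assessment_date = "2013-06-15",
    bathing = 0, personal_hygiene = 0, dressing_upper = 0, dressing_lower = 0,
    walking_indoors = 0, walking_outdoors = 0, locomotion = 0, toilet_use = 0,
    eating = 0, bed_mobility = 0,
    decision_making = 0, short_term_memory_ok = 1, making_self_understood = 0,
    meal_preparation = 0, ordinary_housework = 0, phone_use = 0,
    bladder_incontinence = 0, bowel_incontinence = 0,
    unstable_conditions = 0, caregiver_distress = 0,
    estimated_aide_minutes = 0, estimated_homemaking_minutes = 0,
    age = 78, sex = "F", living_alone = 0, setting = "community",
    on_waitlist_or_hold = 0,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
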