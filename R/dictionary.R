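#' Assessment data dictionary
#'
#' Loads the machine-readable dictionary that defines the assessment CSV
#' layout: one entry per column with its type and admissible codes, levels or
#' numeric range. All parse-time validation is driven by this file so that
#' item coding can be corrected without touching code.
#'
#' @param path Path to a dictionary YAML file. Defaults to the dictionary
#'   bundled with the package.
#' @return A named list with one element per column; each element has fields
#'   `type` and, depending on type, `codes`, `levels`, `min`, `max`,
#'   `required`.
#' @export
psa_dictionary <- function(path = system.file("extdata", "assessment_dictionary.yaml",
                                              package = "psalloc")) {
  stopifnot(nzchar(path), file.exists(path))
  yaml::read_yaml(path)$columns
}

#' ADL self-performance recode table
#'
#' The 0--6/8 self-performance codes are collapsed onto a 0--4 dependence
#' scale before entering the ADL Short Scale and ADL Hierarchy. Code 8
#' ("activity did not occur") is treated as total dependence, a conservative
#' need estimate. The table ships as a CSV resource so it can be corrected
#' without a code change.
#'
#' @param path Path to the recode CSV; defaults to the bundled table.
#' @return A data frame with columns `code`, `recode`, `label`.
#' @export
adl_recode_table <- function(path = system.file("extdata", "adl_self_performance_recode.csv",
                                                package = "psalloc")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Fast lookup vector: names are raw codes, values recodes.
.adl_recode_map <- function() {
  tab <- adl_recode_table()
  stats::setNames(tab$recode, as.character(tab$code))
}
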