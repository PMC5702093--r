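#' Parse a need-group display label
#'
#' Group labels are ordered hierarchically: a higher top-level group
#' represents greater need for personal support. Sublevels A/B/C exist only
#' within Group 1 and order need within it (1A lowest).
#'
#' @param display Character vector of display labels ("1A","1B","1C","2".."6").
#' @return Data frame with columns `display`, `top_level` (integer 1-6) and
#'   `sublevel` (`"A"/"B"/"C"` or `NA`).
#' @export
psa_group <- function(display) {
  display <- as.character(display)
  valid <- c("1A", "1B", "1C", "2", "3", "4", "5", "6")
  bad <- setdiff(unique(display), valid)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  top <- as.integer(substr(display, 1, 1))
  sub <- ifelse(nchar(display) == 2, substr(display, 2, 2), NA_character_)
  data.frame(display = display, top_level = top, sublevel = sub,
             stringsAsFactors = FALSE)
}

# Route rows of `data` through the tree; returns terminal node id per row.
.route <- function(data, tree) {
  n <- nrow(data)
  leaf <- character(n)
  recurse <- function(node_id, idx) {
    node <- tree$nodes[[node_id]]
    if (node$type == "leaf") { leaf[idx] <<- node_id; return(invisible()) }
    x <- data[[node$variable]]
    if (is.null(x)) stop("classifier input '", node$variable, "' missing from data", call. = FALSE)
    x <- x[idx]
    if (anyNA(x)) stop("missing value in classifier input '", node$variable, "'", call. = FALSE)
    assigned <- rep(length(node$children), length(idx))
    for (j in rev(seq_along(node$cuts))) assigned[x < node$cuts[j]] <- j
    for (j in seq_along(node$children)) {
      sel <- idx[assigned == j]
      if (length(sel)) recurse(node$children[j], sel)
    }
  }
  if (n) recurse(tree$root, seq_len(n))
  leaf
}

#' Classify assessment records into need groups
#'
#' Computes scale profiles for the records, routes every row through the
#' decision tree, and returns one group per record. Classification is a pure
#' function of the record and the tree version. Records that cannot be
#' classified (missing classifier inputs under the default `"reject"` missing
#' policy) are reported separately rather than failing the whole cohort.
#'
#' @param records Assessment data frame ([parse_assessments()]), or a data
#'   frame that already carries all classifier input columns (raw items plus
#'   scale columns).
#' @param tree A `psa_treespec`; defaults to the bundled reference tree.
#' @param missing_policy `"reject"` (default) refuses rows with missing
#'   classifier inputs; `"impute_independent"` recodes missing inputs to the
#'   most independent level (0) before classification.
#' @return Data frame with columns `person_id` (when present), `display`,
#'   `top_level`, `sublevel`, `terminal_node_id`, `tree_version`. Attribute
#'   `"distribution"` holds the percentage distribution over display groups
#'   among classified records; attribute `"unclassified"` the row indices
#'   rejected, with reasons.
#' @examples
#' rec <- psa_example_record()                # fully independent
#' classify_cohort(rec)$display               # "1A"
#' @export
classify_cohort <- function(records, tree = psa_reference_tree(),
                            missing_policy = c("reject", "impute_independent")) {
  missing_policy <- match.arg(missing_policy)
  data <- as.data.frame(records)
  vars <- tree_variables(tree)
  scale_cols <- c("self_reliance_impaired", "adl_short", "adl_hierarchy", "cps",
                  "iadl_difficulty")
  missing_scales <- setdiff(intersect(vars, scale_cols), names(data))
  if (length(missing_scales)) {
    prof <- scale_profile(data)
    for (v in missing_scales) data[[v]] <- prof[[v]]
  }

  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("classifier input(s) not in data: ", paste(missing_vars, collapse = ", "), call. = FALSE)

  na_mask <- Reduce(`|`, lapply(vars, function(v) is.na(data[[v]])))
  unclassified <- data.frame(row = integer(), reason = character(), stringsAsFactors = FALSE)
  if (any(na_mask)) {
    if (missing_policy == "reject") {
      na_var <- vapply(which(na_mask), function(i) vars[which(is.na(data[i, vars]))[1]], character(1))
      unclassified <- data.frame(row = which(na_mask),
                                 reason = paste0("missing ", na_var),
                                 stringsAsFactors = FALSE)
    } else {
      for (v in vars) data[[v]][is.na(data[[v]])] <- 0
      na_mask[] <- FALSE
    }
  }

  keep <- which(!na_mask)
  sub <- data[keep, , drop = FALSE]
  leaf_id <- .route(sub, tree)
  leaf_map <- vapply(tree$nodes, function(n)
    if (n$type == "leaf") n$group %||% NA_character_ else NA_character_, character(1))
  grp <- unname(leaf_map[leaf_id])
  if (anyNA(grp)) stop("tree has ungrouped terminal node(s); classify requires a grouped tree", call. = FALSE)
  parsed <- psa_group(grp)

  out <- data.frame(display = parsed$display, top_level = parsed$top_level,
                    sublevel = parsed$sublevel, terminal_node_id = unname(leaf_id),
                    tree_version = rep(tree$version, length(leaf_id)),
                    stringsAsFactors = FALSE)
  if ("person_id" %in% names(sub)) out <- cbind(person_id = sub$person_id, out,
                                                stringsAsFactors = FALSE)
  dist <- if (nrow(out)) {
    tab <- table(out$display)
    round(100 * tab / sum(tab), 4)
  } else table(character(0))
  attr(out, "distribution") <- dist
  attr(out, "unclassified") <- unclassified
  out
}

#' Classify a single record
#'
#' @inheritParams classify_cohort
#' @param record One-row assessment data frame.
#' @return One-row classification data frame (see [classify_cohort()]).
#' @export
classify <- function(record, tree = psa_reference_tree(),
                     missing_policy = c("reject", "impute_independent")) {
  missing_policy <- match.arg(missing_policy)
  res <- classify_cohort(record, tree, missing_policy)
  if (!nrow(res)) {
    why <- attr(res, "unclassified")
    stop("record could not be classified: ", why$reason[1], call. = FALSE)
  }
  res
}
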