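#' Decision-tree specifications
#'
#' The classifier is entirely table-driven: a tree specification is a list of
#' nodes, each either a split node (`variable`, ascending `cuts`, `children`)
#' or a leaf carrying a need-group label. A split with cuts `c(c1, ..., ck)`
#' routes a value `x` to child `j` for the first `j` with `x < cj`, and to the
#' last child otherwise; binary splits have a single cut. This left-closed
#' convention is part of the schema and guarantees deterministic routing.
#'
#' @name tree_spec
NULL

#' Load and validate a tree specification from JSON
#'
#' @param source Path to a JSON file, or an already-parsed list with elements
#'   `root` and `nodes`.
#' @return A validated object of class `psa_treespec`.
#' @seealso [psa_reference_tree()] for the bundled reference tree.
#' @export
load_tree <- function(source) {
  spec <- if (is.character(source)) jsonlite::read_json(source, simplifyVector = FALSE) else source
  nodes <- spec$nodes
  if (is.null(nodes) || !length(nodes)) stop("tree has no nodes", call. = FALSE)
  ids <- vapply(nodes, function(n) n$id %||% NA_character_, character(1))
  if (anyNA(ids) || anyDuplicated(ids)) stop("every node needs a unique id", call. = FALSE)
  names(nodes) <- ids

  # normalise scalar lists from JSON
  nodes <- lapply(nodes, function(n) {
    n$type <- as.character(n$type)
    if (n$type == "split") {
      n$variable <- as.character(n$variable)
      n$cuts <- as.numeric(unlist(n$cuts))
      n$children <- as.character(unlist(n$children))
      if (is.unsorted(n$cuts, strictly = TRUE)) stop("node ", n$id, ": cuts must be strictly increasing", call. = FALSE)
      if (length(n$children) != length(n$cuts) + 1L)
        stop("node ", n$id, ": needs one more child than cuts", call. = FALSE)
    } else if (n$type == "leaf") {
      if (!is.null(n$group)) n$group <- as.character(n$group)
    } else stop("node ", n$id, ": unknown type '", n$type, "'", call. = FALSE)
    n
  })

  root <- as.character(spec$root %||% stop("tree has no root", call. = FALSE))
  if (!root %in% ids) stop("root node '", root, "' not found", call. = FALSE)

  # structural checks: children exist, each node has at most one parent,
  # every node is reachable from the root, no cycles (DFS with path marking)
  child_refs <- unlist(lapply(nodes, function(n) n$children))
  dangling <- setdiff(child_refs, ids)
  if (length(dangling)) stop("dangling child id(s): ", paste(dangling, collapse = ", "), call. = FALSE)
  if (anyDuplicated(child_refs))
    stop("node(s) with multiple parents: ",
         paste(unique(child_refs[duplicated(child_refs)]), collapse = ", "), call. = FALSE)
  if (root %in% child_refs) stop("cycle: root '", root, "' is referenced as a child", call. = FALSE)

  seen <- character(0)
  visit <- function(id, path) {
    if (id %in% path) stop("cycle detected at node '", id, "'", call. = FALSE)
    seen <<- c(seen, id)
    for (ch in nodes[[id]]$children %||% character(0)) visit(ch, c(path, id))
  }
  visit(root, character(0))
  unreachable <- setdiff(ids, seen)
  if (length(unreachable))
    stop("unreachable node(s): ", paste(unreachable, collapse = ", "), call. = FALSE)

  structure(list(version = spec$version %||% "unversioned",
                 provenance = spec$provenance %||% NA_character_,
                 target = spec$target %||% NA_character_,
                 root = root, nodes = nodes),
            class = "psa_treespec")
}

#' Write a tree specification to JSON
#'
#' Inverse of [load_tree()]; `load_tree(save_tree(tree, f))` reproduces the
#' tree exactly.
#'
#' @param tree A `psa_treespec`.
#' @param path Output JSON path.
#' @export
save_tree <- function(tree, path) {
  stopifnot(inherits(tree, "psa_treespec"))
  out <- list(version = tree$version, provenance = tree$provenance,
              target = tree$target, root = tree$root,
              nodes = unname(tree$nodes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' The bundled reference Personal Support Algorithm tree
#'
#' A declared reconstruction of the published six-group algorithm: root split
#' on the Self-Reliance Index; IADL difficulty separating sublevels 1A/1B/1C
#' when the index is not triggered; ADL Short Scale, dressing upper body,
#' decision making and IADL difficulty in the low-impairment branch; cognitive
#' impairment, unstable conditions and bladder incontinence in the moderate
#' branch; bowel incontinence, communication and caregiver distress at the
#' highest ADL impairment. Cut-points are documented data in the JSON file.
#'
#' @return A `psa_treespec`.
#' @export
psa_reference_tree <- function() {
  load_tree(system.file("extdata", "psa_reference_tree.json", package = "psalloc"))
}

#' @export
print.psa_treespec <- function(x, ...) {
  n_leaf <- sum(vapply(x$nodes, function(n) n$type == "leaf", logical(1)))
  groups <- tree_groups(x)
  cat("Decision-tree specification (version ", x$version, ")\n", sep = "")
  cat("  nodes: ", length(x$nodes), " (", n_leaf, " terminal)\n", sep = "")
  if (length(groups)) cat("  groups:", paste(groups, collapse = ", "), "\n")
  invisible(x)
}

#' Terminal-node group labels of a tree
#' @param tree A `psa_treespec`.
#' @return Sorted unique group labels (character), empty if leaves are
#'   ungrouped.
#' @export
tree_groups <- function(tree) {
  g <- unlist(lapply(tree$nodes, function(n) if (n$type == "leaf") n$group else NULL))
  sort(unique(g))
}

#' Variables referenced by a tree
#' @param tree A `psa_treespec`.
#' @return Character vector of split-variable names.
#' @export
tree_variables <- function(tree) {
  unique(unlist(lapply(tree$nodes, function(n) if (n$type == "split") n$variable else NULL)))
}
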