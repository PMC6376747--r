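# Terminology hierarchies: construction, loading, and reachability queries.
# A hierarchy is a rooted DAG of codes with parent -> child edges. Trees
# (ICD) and poly-hierarchies (MeSH, where a descriptor sits at several tree
# positions) are both supported; reachability uses distinct-set semantics so
# multi-path nodes count once.

#' Construct a terminology hierarchy
#'
#' Low-level constructor validating the hierarchy invariants: no self-loops,
#' no duplicate edges, every edge endpoint a known node, and acyclicity.
#' Most users build hierarchies with [build_icd_hierarchy()],
#' [build_mesh_hierarchy()], [load_edge_list()], or [generate_hierarchy()].
#'
#' @param nodes character vector of codes.
#' @param edges data.frame with character columns `parent` and `child`.
#' @param labels named character vector of display labels (names are codes).
#' @param scheme one of `"ICD9"`, `"ICD10"`, `"MESH"`, `"GENERIC"`.
#' @param placeholders codes synthesized for missing intermediate positions.
#' @return an object of class `term_hierarchy`.
#' @export
term_hierarchy <- function(nodes, edges = NULL, labels = NULL,
                           scheme = "GENERIC", placeholders = character(0)) {
  scheme <- match.arg(scheme, CV_SCHEMES)
  nodes <- unique(as.character(nodes))
  if (any(!nzchar(nodes)) || anyNA(nodes)) {
    cv_config_error("hierarchy nodes must be non-empty code strings")
  }
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(parent = as.character(edges$parent),
                        child = as.character(edges$child),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$parent == edges$child)) {
    bad <- edges$parent[edges$parent == edges$child][1L]
    cv_config_error(sprintf("self-loop on node '%s'", bad))
  }
  edges <- unique(edges)
  missing_ep <- setdiff(c(edges$parent, edges$child), nodes)
  if (length(missing_ep)) {
    cv_config_error(sprintf("edge endpoint(s) not in node set: %s",
                            paste(missing_ep, collapse = ", ")))
  }
  cyc <- find_cycle(nodes, edges)
  if (!is.null(cyc)) {
    cv_config_error(sprintf("hierarchy contains a cycle: %s",
                            paste(c(cyc, cyc[1L]), collapse = " -> ")))
  }
  nodes <- sort(nodes)
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges,
                 labels = labels %||% stats::setNames(character(0), character(0)),
                 scheme = scheme, placeholders = placeholders, graph = g),
            class = "term_hierarchy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Iterative DFS cycle finder on the raw edge list (no igraph), so load
# errors can name one offending cycle.
find_cycle <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(NULL)
  kids <- split(edges$child, factor(edges$parent, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, i = 0L))
    path <- character(0)
    state[[start]] <- 1L
    path <- start
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ch <- kids[[top$node]] %||% character(0)
      if (top$i < length(ch)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- ch[[top$i + 1L]]
        if (state[[nxt]] == 1L) {
          return(path[seq(match(nxt, path), length(path))])
        }
        if (state[[nxt]] == 0L) {
          state[[nxt]] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
          path <- c(path, nxt)
        }
      } else {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      }
    }
  }
  NULL
}

#' Build an ICD hierarchy from the codes of a data set
#'
#' ICD-9-CM and ICD-10-CM are mono-hierarchies whose structure is recoverable
#' from code syntax alone: the parent of a code is its longest proper prefix
#' that is itself a syntactically valid code (the dot is dropped when the
#' prefix ends at it), and three-character category codes are roots. All
#' implied prefix ancestors are added, so the result is closed upward.
#'
#' @param codes character vector of ICD codes (normalized internally).
#' @param scheme `"ICD9"` or `"ICD10"`.
#' @return a `term_hierarchy`.
#' @examples
#' h <- build_icd_hierarchy(c("E11.9", "I10"), "ICD10")
#' h$nodes   # "E11" "E11.9" "I10"
#' @export
build_icd_hierarchy <- function(codes, scheme = c("ICD9", "ICD10")) {
  scheme <- match.arg(scheme)
  codes <- normalize_code(codes, scheme)
  if (length(codes) == 0L) return(term_hierarchy(character(0), scheme = scheme))
  bad <- codes[!icd_valid(codes, scheme)]
  if (length(bad)) {
    cv_config_error(sprintf("invalid %s code(s): %s", scheme,
                            paste(unique(bad), collapse = ", ")))
  }
  nodes <- character(0)
  edges_p <- character(0); edges_c <- character(0)
  todo <- unique(codes)
  while (length(todo)) {
    c0 <- todo[[1L]]; todo <- todo[-1L]
    if (c0 %in% nodes) next
    nodes <- c(nodes, c0)
    p <- icd_parent(c0, scheme)
    if (!is.na(p)) {
      edges_p <- c(edges_p, p); edges_c <- c(edges_c, c0)
      if (!(p %in% nodes)) todo <- c(todo, p)
    }
  }
  term_hierarchy(nodes,
                 data.frame(parent = edges_p, child = edges_c,
                            stringsAsFactors = FALSE),
                 scheme = scheme)
}

#' Build a MeSH poly-hierarchy from descriptor/tree-number assignments
#'
#' MeSH addresses each descriptor by one or more dotted tree numbers (e.g.
#' `C04.557.337`); the parent position of a tree number is the tree number
#' with its last segment removed. Edges connect the descriptors occupying
#' those positions, so a descriptor with several tree numbers acquires
#' several parents. When a parent position maps to no known descriptor, a
#' placeholder node (named by the tree-number position) is synthesized by
#' default, or an error is raised with `missing = "error"`.
#'
#' @param assignments data.frame with columns `descriptor`, `tree_number`,
#'   and optionally `label`.
#' @param missing `"placeholder"` (default) or `"error"`.
#' @return a `term_hierarchy` with scheme `"MESH"`; synthesized codes are
#'   listed in its `placeholders` field.
#' @export
build_mesh_hierarchy <- function(assignments, missing = c("placeholder", "error")) {
  missing <- match.arg(missing)
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (nrow(assignments) == 0L) return(term_hierarchy(character(0), scheme = "MESH"))
  desc <- normalize_code(assignments$descriptor, "MESH")
  tree <- trimws(as.character(assignments$tree_number))
  if (any(!grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", tree))) {
    bad <- tree[!grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", tree)][1L]
    cv_config_error(sprintf("malformed tree number '%s'", bad))
  }
  pos <- stats::setNames(desc, tree)
  dup <- tree[duplicated(tree)]
  for (t in dup) {
    if (length(unique(desc[tree == t])) > 1L) {
      cv_config_error(sprintf("tree number '%s' assigned to multiple descriptors", t))
    }
  }
  pos <- pos[!duplicated(names(pos))]

  # synthesize placeholders for every missing ancestor position
  placeholders <- character(0)
  todo <- names(pos)
  while (length(todo)) {
    t <- todo[[1L]]; todo <- todo[-1L]
    pt <- tree_parent(t)
    if (is.na(pt) || pt %in% names(pos)) next
    if (missing == "error") {
      cv_config_error(sprintf(
        "tree position '%s' (parent of '%s') maps to no known descriptor", pt, t))
    }
    pos[[pt]] <- pt
    placeholders <- c(placeholders, pt)
    todo <- c(todo, pt)
  }

  ep <- character(0); ec <- character(0)
  for (t in names(pos)) {
    pt <- tree_parent(t)
    if (is.na(pt)) next
    p <- pos[[pt]]; ch <- pos[[t]]
    if (identical(p, ch)) next  # same descriptor at both positions
    ep <- c(ep, p); ec <- c(ec, ch)
  }
  labels <- character(0)
  if (!is.null(assignments$label)) {
    labels <- stats::setNames(as.character(assignments$label), desc)
    labels <- labels[!duplicated(names(labels)) & nzchar(labels)]
  }
  term_hierarchy(unname(unique(pos)),
                 data.frame(parent = ep, child = ec, stringsAsFactors = FALSE),
                 labels = labels, scheme = "MESH", placeholders = sort(unique(placeholders)))
}

tree_parent <- function(t) {
  parts <- strsplit(t, ".", fixed = TRUE)[[1L]]
  if (length(parts) <= 1L) return(NA_character_)
  paste(parts[-length(parts)], collapse = ".")
}

#' Build a hierarchy from an explicit parent-child edge list
#'
#' @param rows data.frame with character columns `parent`, `child`, and
#'   optionally `label` (a display label for the child code).
#' @param scheme scheme tag to attach; defaults to `"GENERIC"`.
#' @return a `term_hierarchy` with exactly the given edges and their
#'   endpoints. Self-loops and cycles are rejected with an error naming the
#'   offending cycle.
#' @export
load_edge_list <- function(rows, scheme = "GENERIC") {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) return(term_hierarchy(character(0), scheme = scheme))
  labels <- NULL
  if (!is.null(rows$label)) {
    labels <- stats::setNames(as.character(rows$label), as.character(rows$child))
    labels <- labels[nzchar(labels) & !is.na(labels)]
    labels <- labels[!duplicated(names(labels))]
  }
  term_hierarchy(unique(c(rows$parent, rows$child)),
                 rows[c("parent", "child")], labels = labels, scheme = scheme)
}

#' Read a generic terminology edge list from TSV
#'
#' Expects tab-separated columns `parent`, `child`, optional `label`;
#' lines starting with `#` are ignored. A header row is detected when the
#' first data line reads `parent<TAB>child...`.
#'
#' @param path file path.
#' @param scheme scheme tag for the resulting hierarchy.
#' @return a `term_hierarchy`.
#' @export
read_edge_list_tsv <- function(path, scheme = "GENERIC") {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(term_hierarchy(character(0), scheme = scheme))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(trimws(fields[[1L]][1L])) == "parent") fields <- fields[-1L]
  if (length(fields) == 0L) return(term_hierarchy(character(0), scheme = scheme))
  n <- lengths(fields)
  # single-field rows declare isolated nodes; two or more fields are edges
  solo <- trimws(vapply(fields[n == 1L], `[`, "", 1L))
  fields <- fields[n >= 2L]
  rows <- data.frame(parent = trimws(vapply(fields, `[`, "", 1L)),
                     child = trimws(vapply(fields, `[`, "", 2L)),
                     stringsAsFactors = FALSE)
  lab <- vapply(fields, function(f) if (length(f) >= 3L) trimws(f[[3L]]) else "", "")
  keep <- nzchar(rows$child)
  solo <- c(solo, rows$parent[!keep])
  rows <- rows[keep, , drop = FALSE]
  lab <- lab[keep]
  labels <- NULL
  if (any(nzchar(lab))) {
    labels <- stats::setNames(lab, rows$child)
    labels <- labels[nzchar(labels)]
    labels <- labels[!duplicated(names(labels))]
  }
  nodes <- unique(c(rows$parent, rows$child, solo))
  term_hierarchy(nodes[nzchar(nodes)], rows, labels = labels, scheme = scheme)
}

#' Read MeSH descriptor/tree-number assignments from TSV
#'
#' Tab-separated columns `descriptor_id`, `tree_number`, optional `label`;
#' `#` comment lines ignored; header auto-detected.
#'
#' @param path file path.
#' @param missing passed to [build_mesh_hierarchy()].
#' @return a `term_hierarchy` with scheme `"MESH"`.
#' @export
read_mesh_tsv <- function(path, missing = "placeholder") {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(term_hierarchy(character(0), scheme = "MESH"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(trimws(fields[[1L]][1L])) %in% c("descriptor_id", "descriptor")) {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) return(term_hierarchy(character(0), scheme = "MESH"))
  n <- lengths(fields)
  if (any(n < 2L)) {
    cv_io_error(sprintf("MeSH file row %d has fewer than 2 fields", which(n < 2L)[1L]))
  }
  df <- data.frame(descriptor = trimws(vapply(fields, `[`, "", 1L)),
                   tree_number = trimws(vapply(fields, `[`, "", 2L)),
                   stringsAsFactors = FALSE)
  lab <- vapply(fields, function(f) if (length(f) >= 3L) trimws(f[[3L]]) else "", "")
  if (any(nzchar(lab))) df$label <- lab
  build_mesh_hierarchy(df, missing = missing)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) cv_io_error(sprintf("cannot read file '%s'", path))
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Write a hierarchy to a generic edge-list TSV
#' @param h a `term_hierarchy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list_tsv <- function(h, path) {
  stopifnot(inherits(h, "term_hierarchy"))
  lines <- c("parent\tchild",
             sprintf("%s\t%s", h$edges$parent, h$edges$child))
  # isolated nodes are kept as single-field rows so a round trip preserves
  # the node set
  isolated <- setdiff(h$nodes, c(h$edges$parent, h$edges$child))
  if (length(isolated)) lines <- c(lines, isolated)
  writeLines(lines[!duplicated(lines)], path, useBytes = TRUE)
  invisible(path)
}

#' Proper ancestors of a code
#'
#' All distinct codes from which `code` is reachable along parent-to-child
#' edges, excluding `code` itself; in a poly-hierarchy a node reachable via
#' several paths is returned once.
#'
#' @param h a `term_hierarchy`.
#' @param code a single code present in `h`.
#' @return character vector of ancestor codes (sorted).
#' @export
ancestors <- function(h, code) reachable(h, code, mode = "in")

#' Proper descendants of a code
#'
#' All distinct codes reachable from `code` along parent-to-child edges,
#' excluding `code` itself. This is the set whose NC values the class count
#' (CC) sums.
#'
#' @inheritParams ancestors
#' @return character vector of descendant codes (sorted).
#' @export
descendants <- function(h, code) reachable(h, code, mode = "out")

reachable <- function(h, code, mode) {
  stopifnot(inherits(h, "term_hierarchy"))
  if (length(code) != 1L || !(code %in% h$nodes)) {
    cv_config_error(sprintf("unknown code '%s'", paste(code, collapse = ",")))
  }
  vs <- igraph::subcomponent(h$graph, code, mode = mode)
  sort(setdiff(names(vs), code))
}

# Roots: nodes with no incoming edge.
hierarchy_roots <- function(h) sort(setdiff(h$nodes, unique(h$edges$child)))

#' @export
print.term_hierarchy <- function(x, ...) {
  cat(sprintf("<term_hierarchy> scheme=%s: %d nodes, %d edges, %d root(s)\n",
              x$scheme, length(x$nodes), nrow(x$edges), length(hierarchy_roots(x))))
  if (length(x$placeholders)) {
    cat(sprintf("  placeholders synthesized for %d missing position(s)\n",
                length(x$placeholders)))
  }
  invisible(x)
}
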