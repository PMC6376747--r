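# Summary views: ancestor-closed induced subgraphs of the hierarchy with
# per-node metric annotations, color scaling, and serialization to DOT,
# GraphML, and CSV. A view contains the filter-passing nodes plus all their
# ancestors (never descendants), and exactly the source edges between view
# members.

#' Build an ancestor-closed summary view
#'
#' The view's node set is the selection closed upward (every ancestor of a
#' selected code is pulled in); its edges are the hierarchy edges whose two
#' endpoints are both in the view. Annotations carry nc, cc, max_ratio, the
#' selected flag, and a tooltip; colors are assigned separately with
#' [assign_colors()].
#'
#' @param h the source `term_hierarchy`.
#' @param metrics `node_metrics` computed over `h`.
#' @param sel a `node_selection` with codes from `h`.
#' @param title view title (used in DOT output).
#' @return an object of class `summary_view`.
#' @examples
#' h <- load_edge_list(data.frame(parent = c("A", "B"), child = c("B", "C")))
#' m <- node_metrics(coded_dataset(c(C = 5)), h)
#' v <- build_summary_view(h, m, select_threshold(m, "NC", 1))
#' v$nodes  # "A" "B" "C": ancestors of C pulled in
#' @export
build_summary_view <- function(h, metrics, sel, title = "summary view") {
  stopifnot(inherits(h, "term_hierarchy"), inherits(metrics, "node_metrics"),
            inherits(sel, "node_selection"))
  outside <- setdiff(sel$codes, h$nodes)
  if (length(outside)) {
    cv_config_error(sprintf("selection code(s) not in hierarchy: %s",
                            paste(outside, collapse = ", ")))
  }
  nodes <- sel$codes
  for (c0 in sel$codes) nodes <- union(nodes, ancestors(h, c0))
  nodes <- sort(nodes)
  keep <- h$edges$parent %in% nodes & h$edges$child %in% nodes
  edges <- h$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  mr <- max_ratio_per_node(metrics, nodes)
  ann <- data.frame(
    code = nodes,
    label = label_or_code(h, nodes),
    nc = as.numeric(metrics$nc[nodes]),
    cc = as.numeric(metrics$cc[nodes]),
    max_ratio = as.numeric(mr),
    selected = nodes %in% sel$codes,
    color = rep(NA_character_, length(nodes)),
    stringsAsFactors = FALSE)
  ann$tooltip <- sprintf("nc=%s; cc=%s; max_ratio=%s",
                         format_num(ann$nc), format_num(ann$cc),
                         ifelse(is.na(ann$max_ratio), "-", fmt_real(ann$max_ratio)))
  rownames(ann) <- NULL
  structure(list(nodes = nodes, edges = edges, annotations = ann,
                 title = title, scheme = h$scheme),
            class = "summary_view")
}

label_or_code <- function(h, nodes) {
  lab <- unname(h$labels[nodes])
  ifelse(is.na(lab) | !nzchar(lab), nodes, lab)
}

#' Build a comparison view
#'
#' Reuses the summary-view machinery for a two-data-set comparison: the
#' selected codes are the retained comparison records (typically from
#' [top_differences()]), the coloring key is the difference score, and the
#' tooltip carries the signed delta so the direction of the difference is
#' visible.
#'
#' @param h the shared `term_hierarchy`.
#' @param records a `cc_comparison` (usually already truncated).
#' @param title view title.
#' @return a `summary_view` whose annotations include a `score` column.
#' @export
build_comparison_view <- function(h, records, title = "comparison view") {
  stopifnot(inherits(h, "term_hierarchy"), inherits(records, "cc_comparison"))
  sel <- new_selection(records$code, list(key = "SCORE", mode = "top", value = nrow(records)))
  nodes <- sel$codes
  for (c0 in sel$codes) nodes <- union(nodes, ancestors(h, c0))
  nodes <- sort(nodes)
  keep <- h$edges$parent %in% nodes & h$edges$child %in% nodes
  edges <- h$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  i <- match(nodes, records$code)
  ann <- data.frame(
    code = nodes,
    label = label_or_code(h, nodes),
    nc = rep(NA_real_, length(nodes)),
    cc = ifelse(is.na(i), NA_real_, records$cc_a[i]),
    max_ratio = rep(NA_real_, length(nodes)),
    selected = nodes %in% sel$codes,
    color = rep(NA_character_, length(nodes)),
    score = ifelse(is.na(i), 0, records$score[i]),
    stringsAsFactors = FALSE)
  delta <- ifelse(is.na(i), NA_real_, records$delta[i])
  ann$tooltip <- ifelse(is.na(delta), "ancestor (not compared)",
                        sprintf("cc_a=%s; cc_b=%s; delta=%s%s",
                                format_num(ifelse(is.na(i), 0, records$cc_a[i])),
                                format_num(ifelse(is.na(i), 0, records$cc_b[i])),
                                ifelse(delta >= 0, "+", ""), fmt_real(delta)))
  rownames(ann) <- NULL
  structure(list(nodes = nodes, edges = edges, annotations = ann,
                 title = title, scheme = h$scheme),
            class = "summary_view")
}

#' Assign a red-to-green color scale to a view
#'
#' The node with the maximal key value maps to pure red, the minimal to
#' pure green, and the rest are interpolated channel-wise in RGB between
#' the two endpoints (red marks high values, green low). With
#' `scale = "log"` the interpolation parameter is computed on `log1p` of
#' the values, which spreads heavy-tailed CC distributions. A
#' constant-valued view maps uniformly to green.
#'
#' @param view a `summary_view`.
#' @param key `"CC"`, `"NC"`, or `"score"` (comparison views).
#' @param scale `"linear"` or `"log"`.
#' @return the view with hex colors filled into its annotations.
#' @export
assign_colors <- function(view, key = c("CC", "NC", "score"),
                          scale = c("linear", "log")) {
  stopifnot(inherits(view, "summary_view"))
  key <- match.arg(key); scale <- match.arg(scale)
  ann <- view$annotations
  vals <- switch(key, CC = ann$cc, NC = ann$nc, score = ann$score)
  if (is.null(vals)) cv_config_error(sprintf("view has no '%s' annotation", key))
  vals[is.na(vals)] <- 0
  if (nrow(ann) == 0L) return(view)
  if (scale == "log") vals <- log1p(vals)
  rng <- range(vals)
  t <- if (diff(rng) == 0) rep(0, length(vals)) else (vals - rng[1L]) / diff(rng)
  red <- round(255 * t)
  green <- round(255 * (1 - t))
  view$annotations$color <- sprintf("#%02X%02X00", red, green)
  view
}

dot_escape <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))

#' Serialize a view to Graphviz DOT
#'
#' Emits a directed graph with top-to-bottom rank direction, one node
#' statement per code (label, fill color, tooltip with the metric values)
#' and one edge statement per induced edge. Nodes and edges are emitted in
#' sorted order, so output is byte-identical across runs. Render to
#' PNG/SVG with [render_view()] when Graphviz is installed.
#'
#' @param view a `summary_view`.
#' @param path output path; `NULL` returns the DOT text.
#' @return the DOT text (or `path`), invisibly when written.
#' @export
export_dot <- function(view, path = NULL) {
  stopifnot(inherits(view, "summary_view"))
  ann <- view$annotations
  node_lines <- sprintf('  "%s" [label="%s", style=filled, fillcolor="%s", tooltip="%s"];',
                        dot_escape(ann$code), dot_escape(ann$label),
                        ifelse(is.na(ann$color), "#FFFFFF", ann$color),
                        dot_escape(ann$tooltip))
  e <- view$edges
  edge_lines <- if (nrow(e)) sprintf('  "%s" -> "%s";',
                                     dot_escape(e$parent), dot_escape(e$child))
                else character(0)
  lines <- c("digraph summary_view {",
             sprintf('  label="%s";', dot_escape(view$title)),
             "  rankdir=TB;",
             "  node [shape=box, fontname=\"Helvetica\"];",
             node_lines, edge_lines, "}")
  emit_text(lines, path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Serialize a view to GraphML
#'
#' Deterministic GraphML mirror of [export_dot()], with node data keys for
#' label, nc, cc, max_ratio, selected, and color.
#'
#' @inheritParams export_dot
#' @return the GraphML text (or `path`), invisibly when written.
#' @export
export_graphml <- function(view, path = NULL) {
  stopifnot(inherits(view, "summary_view"))
  ann <- view$annotations
  keys <- c('  <key id="label" for="node" attr.name="label" attr.type="string"/>',
            '  <key id="nc" for="node" attr.name="nc" attr.type="double"/>',
            '  <key id="cc" for="node" attr.name="cc" attr.type="double"/>',
            '  <key id="max_ratio" for="node" attr.name="max_ratio" attr.type="double"/>',
            '  <key id="selected" for="node" attr.name="selected" attr.type="boolean"/>',
            '  <key id="color" for="node" attr.name="color" attr.type="string"/>')
  nodes <- unlist(lapply(seq_len(nrow(ann)), function(i) c(
    sprintf('    <node id="%s">', xml_escape(ann$code[i])),
    sprintf('      <data key="label">%s</data>', xml_escape(ann$label[i])),
    sprintf('      <data key="nc">%s</data>', format_num(ann$nc[i])),
    sprintf('      <data key="cc">%s</data>', format_num(ann$cc[i])),
    if (!is.na(ann$max_ratio[i]))
      sprintf('      <data key="max_ratio">%s</data>', fmt_real(ann$max_ratio[i])),
    sprintf('      <data key="selected">%s</data>', tolower(ann$selected[i])),
    if (!is.na(ann$color[i]))
      sprintf('      <data key="color">%s</data>', ann$color[i]),
    "    </node>")))
  e <- view$edges
  edges <- if (nrow(e)) sprintf('    <edge source="%s" target="%s"/>',
                                xml_escape(e$parent), xml_escape(e$child))
           else character(0)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             keys,
             '  <graph id="summary_view" edgedefault="directed">',
             nodes, edges,
             "  </graph>", "</graphml>")
  emit_text(lines, path)
}

#' Export a view's node table to CSV
#'
#' One row per view node, sorted by code: code, label, nc, cc, max_ratio,
#' selected.
#'
#' @inheritParams export_dot
#' @return the CSV text (or `path`), invisibly when written.
#' @export
export_view_csv <- function(view, path = NULL) {
  stopifnot(inherits(view, "summary_view"))
  ann <- view$annotations[order(view$annotations$code), , drop = FALSE]
  lines <- c("code,label,nc,cc,max_ratio,selected",
             sprintf("%s,%s,%s,%s,%s,%s",
                     ann$code, csv_field(ann$label),
                     ifelse(is.na(ann$nc), "", format_num(ann$nc)),
                     ifelse(is.na(ann$cc), "", format_num(ann$cc)),
                     ifelse(is.na(ann$max_ratio), "", fmt_real(ann$max_ratio)),
                     ifelse(ann$selected, "TRUE", "FALSE")))
  emit_text(lines, path)
}

#' Is a Graphviz renderer available?
#' @return `TRUE` when the `dot` executable is on the PATH.
#' @export
has_graphviz <- function() nzchar(Sys.which("dot"))

#' Render a view to PNG or SVG via Graphviz
#'
#' Writes the DOT serialization and invokes the external `dot` renderer.
#' Rendering is optional: the computed artifacts (DOT, GraphML, CSV) do not
#' depend on it.
#'
#' @param view a `summary_view`.
#' @param path output image path.
#' @param format `"png"` or `"svg"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
render_view <- function(view, path, format = NULL) {
  if (!has_graphviz()) {
    cv_io_error("Graphviz 'dot' executable not found on PATH; export DOT instead")
  }
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("png", "svg"))
  dotfile <- tempfile(fileext = ".dot")
  on.exit(unlink(dotfile))
  export_dot(view, dotfile)
  status <- system2(Sys.which("dot"), c(paste0("-T", format), dotfile, "-o", path))
  if (status != 0L) cv_io_error(sprintf("dot exited with status %d", status))
  invisible(path)
}

#' @export
print.summary_view <- function(x, ...) {
  cat(sprintf("<summary_view> '%s': %d nodes (%d selected), %d edges\n",
              x$title, length(x$nodes), sum(x$annotations$selected),
              nrow(x$edges)))
  invisible(x)
}
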