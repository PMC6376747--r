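# Core analytics: node counts (NC), class counts (CC), child/parent CC
# ratios, and the filtering algorithms (threshold, top-k, top-percent,
# ratio, combinations) with a threshold-tuning preview.

#' Node counts over a hierarchy
#'
#' NC is the raw usage frequency of a code in the data set; a hierarchy
#' node absent from the data set (e.g. an implied ancestor) has NC 0, so
#' the NC map always covers every node and its total equals the event
#' count.
#'
#' @param ds a `coded_dataset`.
#' @param h a `term_hierarchy` containing every code of `ds`.
#' @return named numeric vector over all nodes of `h`.
#' @export
compute_nc <- function(ds, h) {
  stopifnot(inherits(ds, "coded_dataset"), inherits(h, "term_hierarchy"))
  entries <- dataset_entries(ds)
  missing <- setdiff(names(entries), h$nodes)
  if (length(missing)) {
    cv_config_error(sprintf("data set code(s) not in hierarchy: %s",
                            paste(missing, collapse = ", ")))
  }
  nc <- stats::setNames(numeric(length(h$nodes)), h$nodes)
  nc[names(entries)] <- entries
  nc
}

#' Class counts: rollup of NC over distinct descendants
#'
#' For each node, CC is the sum of NC over its distinct proper descendants;
#' in a poly-hierarchy a descendant reachable along several paths
#' contributes once. With `include_self = TRUE` the node's own NC is added,
#' the convention under which the root of a tree carries the full event
#' count.
#'
#' @param nc named numeric vector covering all nodes of `h`
#'   (from [compute_nc()]).
#' @param h the `term_hierarchy`.
#' @param include_self add the node's own NC to its CC (default `FALSE`:
#'   descendants only, so leaves have CC 0).
#' @return named numeric vector over all nodes of `h`.
#' @export
compute_cc <- function(nc, h, include_self = FALSE) {
  stopifnot(inherits(h, "term_hierarchy"))
  if (!all(h$nodes %in% names(nc))) {
    cv_config_error("nc must cover every hierarchy node")
  }
  nc <- nc[h$nodes]
  n <- length(h$nodes)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  # distinct-descendant reachability: finite positive distance in the DAG
  d <- igraph::distances(h$graph, mode = "out")[h$nodes, h$nodes, drop = FALSE]
  reach <- is.finite(d) & d > 0
  cc <- as.numeric(reach %*% nc)
  if (include_self) cc <- cc + nc
  stats::setNames(cc, h$nodes)
}

#' Per-edge child/parent CC ratios
#'
#' Ratio = CC(child) / CC(parent) for every hierarchy edge whose parent has
#' positive CC; edges with parent CC 0 are omitted (the ratio is
#' undefined). All values lie in \[0, 1\] because a child's class is a
#' subset of its parent's.
#'
#' @param cc named numeric vector from [compute_cc()].
#' @param h the `term_hierarchy`.
#' @return data.frame with columns `child`, `parent`, `ratio`.
#' @export
compute_ratio <- function(cc, h) {
  stopifnot(inherits(h, "term_hierarchy"))
  if (!all(h$nodes %in% names(cc))) {
    cv_config_error("cc must cover every hierarchy node")
  }
  e <- h$edges
  keep <- cc[e$parent] > 0
  data.frame(child = e$child[keep], parent = e$parent[keep],
             ratio = as.numeric(cc[e$child][keep] / cc[e$parent][keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compute all node metrics for one data set over one hierarchy
#'
#' Convenience wrapper producing the NC, CC, and ratio maps together.
#'
#' @inheritParams compute_nc
#' @inheritParams compute_cc
#' @return an object of class `node_metrics`: list with `nc`, `cc`, `ratio`
#'   (per-edge data.frame), `include_self`, `hierarchy`, and provenance
#'   tags.
#' @examples
#' h <- load_edge_list(data.frame(parent = c("A", "B"), child = c("B", "C")))
#' ds <- coded_dataset(c(B = 2, C = 3))
#' m <- node_metrics(ds, h)
#' m$cc  # A: 5, B: 3, C: 0
#' @export
node_metrics <- function(ds, h, include_self = FALSE) {
  nc <- compute_nc(ds, h)
  cc <- compute_cc(nc, h, include_self = include_self)
  structure(list(nc = nc, cc = cc, ratio = compute_ratio(cc, h),
                 include_self = include_self, hierarchy = h,
                 dataset_ref = ds$source_name),
            class = "node_metrics")
}

#' @export
print.node_metrics <- function(x, ...) {
  cat(sprintf("<node_metrics> %d nodes, include_self=%s; max NC %s, max CC %s\n",
              length(x$nc), x$include_self,
              format_num(if (length(x$nc)) max(x$nc) else NA),
              format_num(if (length(x$cc)) max(x$cc) else NA)))
  invisible(x)
}

metric_vector <- function(metrics, key) {
  key <- toupper(key)
  switch(key, NC = metrics$nc, CC = metrics$cc,
         cv_config_error(sprintf("unknown metric key '%s'", key)))
}

new_selection <- function(codes, criterion) {
  structure(list(codes = sort(unique(codes)), criterion = criterion),
            class = "node_selection")
}

#' @export
print.node_selection <- function(x, ...) {
  cat(sprintf("<node_selection> %d code(s); criterion: %s\n", length(x$codes),
              paste(names(x$criterion), unlist(lapply(x$criterion, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Select the top nodes by NC or CC
#'
#' The candidate pool is the set of nodes with a positive value of the
#' chosen metric, so structural ancestors with zero counts never crowd the
#' ranking. In count mode the top `value` candidates are returned (capped
#' at the pool size); in percent mode the top `ceiling(value/100 * pool)`.
#' Ties at the cutoff break lexicographically by code, so repeated calls
#' are identical.
#'
#' @param metrics a `node_metrics` object.
#' @param key `"NC"` or `"CC"`.
#' @param mode `"count"` or `"percent"`.
#' @param value positive number; a percentage (<= 100) in percent mode.
#' @return a `node_selection`.
#' @export
select_top <- function(metrics, key = c("NC", "CC"), mode = c("count", "percent"),
                       value) {
  key <- toupper(key[1L]); mode <- match.arg(mode)
  m <- metric_vector(metrics, key)
  if (!is.numeric(value) || length(value) != 1L || value <= 0) {
    cv_config_error("top-node value must be a positive number")
  }
  if (mode == "percent" && value > 100) {
    cv_config_error("percent value must be <= 100")
  }
  pool <- m[m > 0]
  k <- if (mode == "count") min(floor(value), length(pool))
       else ceiling(value / 100 * length(pool))
  ord <- order(-pool, names(pool))
  new_selection(names(pool)[ord][seq_len(k)],
                list(key = key, mode = mode, value = value))
}

#' Select nodes at or above a metric threshold
#'
#' @param metrics a `node_metrics` object.
#' @param key `"NC"` or `"CC"`.
#' @param threshold non-negative count; nodes with metric >= threshold are
#'   selected (threshold 0 selects every node).
#' @return a `node_selection`.
#' @export
select_threshold <- function(metrics, key = c("NC", "CC"), threshold) {
  key <- toupper(key[1L])
  m <- metric_vector(metrics, key)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    cv_config_error("threshold must be a non-negative number")
  }
  new_selection(names(m)[m >= threshold],
                list(key = key, mode = "threshold", value = threshold))
}

#' Select the largest contributors by CC ratio
#'
#' Selects child nodes having at least one incident edge whose
#' CC(child)/CC(parent) ratio reaches the threshold (any-parent rule in
#' poly-hierarchies). Edges whose parent has CC 0 carry no ratio and never
#' qualify.
#'
#' @param metrics a `node_metrics` object.
#' @param threshold ratio threshold in \[0, 1\].
#' @return a `node_selection`.
#' @export
select_ratio <- function(metrics, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    cv_config_error("ratio threshold must lie in [0, 1]")
  }
  r <- metrics$ratio
  new_selection(unique(r$child[r$ratio >= threshold]),
                list(key = "RATIO", mode = "threshold", value = threshold))
}

#' Combine selections by union or intersection
#'
#' Implements the combination filters (e.g. most frequently used codes
#' together with the largest contributors): the union (default) or
#' intersection of the member code sets.
#'
#' @param selections non-empty list of `node_selection` objects.
#' @param mode `"union"` or `"intersection"`.
#' @return a `node_selection` whose criterion records the combination.
#' @export
combine_selections <- function(selections, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!is.list(selections) || length(selections) == 0L ||
      inherits(selections, "node_selection")) {
    if (inherits(selections, "node_selection")) selections <- list(selections)
    else cv_config_error("combine_selections needs at least one selection")
  }
  sets <- lapply(selections, function(s) {
    stopifnot(inherits(s, "node_selection")); s$codes
  })
  codes <- Reduce(if (mode == "union") union else intersect, sets)
  new_selection(codes, list(key = "COMBINED", mode = mode,
                            value = length(selections)))
}

#' Preview a metric distribution for threshold tuning
#'
#' Summarizes the nonzero values of NC or CC — sorted values, quantiles,
#' and the number of nodes surviving each of a ladder of candidate
#' thresholds — so a user can pick a cutoff before running a filter.
#'
#' @param metrics a `node_metrics` object.
#' @param key `"NC"` or `"CC"`.
#' @param thresholds optional numeric vector of candidate thresholds; by
#'   default 10 values evenly spaced over the nonzero range.
#' @return list with `values` (nonzero, decreasing), `quantiles` (min, 5%,
#'   25%, 50%, 75%, 95%, max), `ladder` (data.frame threshold/survivors),
#'   and `no_nonzero` flag.
#' @export
preview_distribution <- function(metrics, key = c("NC", "CC"), thresholds = NULL) {
  key <- toupper(key[1L])
  m <- metric_vector(metrics, key)
  vals <- sort(m[m > 0], decreasing = TRUE)
  if (length(vals) == 0L) {
    return(list(key = key, values = numeric(0), quantiles = NULL,
                ladder = data.frame(threshold = numeric(0), survivors = integer(0)),
                no_nonzero = TRUE))
  }
  qs <- stats::quantile(vals, probs = c(0, .05, .25, .5, .75, .95, 1), names = FALSE)
  names(qs) <- c("min", "p5", "p25", "median", "p75", "p95", "max")
  if (is.null(thresholds)) {
    thresholds <- unique(seq(min(vals), max(vals), length.out = 10L))
  }
  ladder <- data.frame(threshold = thresholds,
                       survivors = vapply(thresholds,
                                          function(t) sum(vals >= t), integer(1)))
  list(key = key, values = unname(vals), quantiles = qs, ladder = ladder,
       no_nonzero = FALSE)
}

# max over incident as-child edges; NA when the node carries no ratio
max_ratio_per_node <- function(metrics, nodes) {
  r <- metrics$ratio
  out <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  if (nrow(r)) {
    mx <- tapply(r$ratio, r$child, max)
    hit <- intersect(nodes, names(mx))
    out[hit] <- mx[hit]
  }
  out
}

#' Export node metrics to CSV
#'
#' One row per hierarchy node: code, label, nc, cc, max_ratio (largest
#' incident child-edge ratio, empty when none), selected flag.
#'
#' @param metrics a `node_metrics` object.
#' @param path output path; `NULL` returns the CSV text.
#' @param selection optional `node_selection` controlling the
#'   `selected` column (default: none selected).
#' @return `path` (or the CSV text when `path` is `NULL`), invisibly.
#' @export
write_metrics_csv <- function(metrics, path = NULL, selection = NULL) {
  stopifnot(inherits(metrics, "node_metrics"))
  h <- metrics$hierarchy
  nodes <- h$nodes
  mr <- max_ratio_per_node(metrics, nodes)
  sel <- if (is.null(selection)) rep(FALSE, length(nodes)) else nodes %in% selection$codes
  lines <- c("code,label,nc,cc,max_ratio,selected",
             sprintf("%s,%s,%s,%s,%s,%s",
                     nodes, csv_field(unname(h$labels[nodes])),
                     format_num(metrics$nc[nodes]), format_num(metrics$cc[nodes]),
                     ifelse(is.na(mr), "", format_num(mr)),
                     ifelse(sel, "TRUE", "FALSE")))
  emit_text(lines, path)
}

csv_field <- function(x) {
  x[is.na(x)] <- ""
  needs <- grepl('[",\n]', x)
  x[needs] <- sprintf('"%s"', gsub('"', '""', x[needs]))
  x
}

emit_text <- function(lines, path) {
  if (is.null(path)) return(paste0(paste(lines, collapse = "\n"), "\n"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
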