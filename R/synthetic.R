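# Seeded synthetic fixtures: random rooted hierarchies (trees, optionally
# poly-hierarchies via extra cross edges) and Zipf-distributed coded data
# sets. Clinical code usage is heavy-tailed, hence the Zipf frequency
# model; the exponent is configurable so tests can probe flat and skewed
# regimes.

#' Configuration for the synthetic generators
#'
#' @param n_nodes number of hierarchy nodes (>= 1).
#' @param max_children maximum children per node in the base tree (>= 1).
#' @param poly_fraction fraction of non-root nodes receiving a second
#'   parent via a cross edge, in \[0, 1\]; 0 yields a tree.
#' @param n_events total event count of a generated data set (>= 0).
#' @param zipf_exponent exponent of the Zipf frequency weights (> 0);
#'   larger values concentrate events on fewer codes.
#' @param seed integer RNG seed; identical configurations generate
#'   identical hierarchies and data sets.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_nodes = 60L, max_children = 4L,
                             poly_fraction = 0, n_events = 2000L,
                             zipf_exponent = 1.2, seed = 1L) {
  if (n_nodes < 1L) cv_config_error("n_nodes must be >= 1")
  if (max_children < 1L) cv_config_error("max_children must be >= 1")
  if (poly_fraction < 0 || poly_fraction > 1) {
    cv_config_error("poly_fraction must lie in [0, 1]")
  }
  if (n_events < 0L) cv_config_error("n_events must be >= 0")
  if (zipf_exponent <= 0) cv_config_error("zipf_exponent must be > 0")
  structure(list(n_nodes = as.integer(n_nodes),
                 max_children = as.integer(max_children),
                 poly_fraction = poly_fraction,
                 n_events = as.integer(n_events),
                 zipf_exponent = zipf_exponent,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# run expr under a local RNG state seeded deterministically
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random rooted hierarchy
#'
#' Builds a rooted tree by preferential attachment (a new node picks an
#' existing parent with probability proportional to one plus its current
#' child count) bounded by `max_children`, then adds
#' `round(poly_fraction * (n_nodes - 1))` cross edges. A cross edge runs
#' from a node to a non-descendant non-ancestor, so acyclicity is
#' guaranteed by construction and the target gains a second parent.
#'
#' @param cfg a `generator_config`.
#' @return a `term_hierarchy` with scheme `"GENERIC"` and node codes
#'   `N0001`, `N0002`, ...
#' @export
generate_hierarchy <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_nodes
  nodes <- sprintf("N%04d", seq_len(n))
  if (n == 1L) return(term_hierarchy(nodes, scheme = "GENERIC"))
  with_seed(cfg$seed, {
    parent_of <- character(n); parent_of[1L] <- NA_character_
    child_count <- integer(n)
    for (i in 2:n) {
      eligible <- which(child_count[seq_len(i - 1L)] < cfg$max_children)
      if (length(eligible) == 0L) {
        cv_config_error("max_children infeasible for n_nodes")
      }
      w <- child_count[eligible] + 1L
      p <- eligible[sample.int(length(eligible), 1L, prob = w)]
      parent_of[i] <- nodes[p]
      child_count[p] <- child_count[p] + 1L
    }
    ep <- parent_of[-1L]; ec <- nodes[-1L]
    n_extra <- round(cfg$poly_fraction * (n - 1L))
    added <- 0L; attempts <- 0L
    kids <- split(ec, factor(ep, levels = nodes))
    desc_of <- function(u) {
      seen <- character(0); todo <- u
      while (length(todo)) {
        x <- todo[[1L]]; todo <- todo[-1L]
        ch <- kids[[x]] %||% character(0)
        new <- setdiff(ch, seen)
        seen <- c(seen, new); todo <- c(todo, new)
      }
      seen
    }
    while (added < n_extra && attempts < 200L * n) {
      attempts <- attempts + 1L
      u <- nodes[sample.int(n, 1L)]
      v <- nodes[sample.int(n, 1L)]
      if (identical(u, v)) next
      if (v %in% (kids[[u]] %||% character(0))) next         # duplicate edge
      if (u %in% desc_of(v)) next                             # would close a cycle
      if (v %in% desc_of(u)) next                             # keep cross edges lateral
      ep <- c(ep, u); ec <- c(ec, v)
      kids[[u]] <- c(kids[[u]], v)
      added <- added + 1L
    }
    term_hierarchy(nodes, data.frame(parent = ep, child = ec,
                                     stringsAsFactors = FALSE),
                   scheme = "GENERIC")
  })
}

#' Generate a Zipf-distributed coded data set over a hierarchy
#'
#' Assigns `n_events` events to nodes drawn from a Zipf-like distribution
#' (weight of the k-th node in a random ordering proportional to
#' `k^-zipf_exponent`); frequencies sum exactly to `n_events`.
#'
#' @param h a non-empty `term_hierarchy`.
#' @param cfg a `generator_config` (its `n_events`, `zipf_exponent`, and
#'   `seed` are used).
#' @return a `coded_dataset` with one entry per hierarchy node.
#' @export
generate_dataset <- function(h, cfg) {
  stopifnot(inherits(h, "term_hierarchy"), inherits(cfg, "generator_config"))
  if (length(h$nodes) == 0L) cv_config_error("hierarchy is empty")
  with_seed(cfg$seed + 1L, {
    ord <- sample(h$nodes)
    w <- seq_along(ord)^(-cfg$zipf_exponent)
    freq <- as.integer(stats::rmultinom(1L, cfg$n_events, w / sum(w)))
    coded_dataset(stats::setNames(freq, ord), scheme = h$scheme,
                  source_name = sprintf("synthetic(seed=%d)", cfg$seed))
  })
}
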