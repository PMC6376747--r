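# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's reachability path (igraph): they are plain recursive DFS
# over the raw edge list.

chain_hierarchy <- function(codes = c("A", "B", "C")) {
  load_edge_list(data.frame(parent = codes[-length(codes)],
                            child = codes[-1L], stringsAsFactors = FALSE))
}

diamond_hierarchy <- function() {
  load_edge_list(data.frame(parent = c("A", "A", "B", "C"),
                            child = c("B", "C", "D", "D"),
                            stringsAsFactors = FALSE))
}

# naive per-node DFS over the edge list; mode "out" = descendants
oracle_reach <- function(h, node, mode = c("out", "in")) {
  mode <- match.arg(mode)
  e <- h$edges
  step <- function(x) if (mode == "out") e$child[e$parent == x] else e$parent[e$child == x]
  seen <- character(0)
  todo <- step(node)
  while (length(todo)) {
    x <- todo[[1L]]; todo <- todo[-1L]
    if (x %in% seen) next
    seen <- c(seen, x)
    todo <- c(todo, step(x))
  }
  sort(seen)
}

oracle_cc <- function(h, nc, include_self = FALSE) {
  vapply(h$nodes, function(n) {
    s <- sum(nc[oracle_reach(h, n, "out")])
    if (include_self) s + nc[[n]] else s
  }, numeric(1))
}

random_case <- function(seed, n_nodes = NULL, poly = NULL, n_events = 500L) {
  set.seed(seed)
  n <- n_nodes %||% sample(2:60, 1L)
  p <- poly %||% sample(c(0, 0.1, 0.3), 1L)
  cfg <- generator_config(n_nodes = n, max_children = sample(2:5, 1L),
                          poly_fraction = p, n_events = n_events,
                          zipf_exponent = runif(1, 0.5, 2), seed = seed)
  h <- generate_hierarchy(cfg)
  list(cfg = cfg, h = h, ds = generate_dataset(h, cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_toy_csv <- function(path, rows = c("E11.9,4559", "I10,3000"), header = TRUE) {
  writeLines(c(if (header) "code,frequency", rows), path)
}
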