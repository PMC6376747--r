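view_fixture <- function() {
  h <- chain_hierarchy()
  m <- node_metrics(coded_dataset(c(B = 2, C = 3)), h, include_self = TRUE)
  list(h = h, m = m)
}

test_that("summary views are ancestor-closed induced subgraphs", {
  fx <- view_fixture()
  sel <- codeviews:::new_selection("C", list(key = "NC"))
  v <- build_summary_view(fx$h, fx$m, sel)
  expect_equal(v$nodes, c("A", "B", "C"))
  expect_equal(nrow(v$edges), 2L)
  expect_equal(v$annotations$selected, c(FALSE, FALSE, TRUE))

  # root-only selection: single node, no edges
  vr <- build_summary_view(fx$h, fx$m, codeviews:::new_selection("A", list()))
  expect_equal(vr$nodes, "A")
  expect_equal(nrow(vr$edges), 0L)

  # diamond closure pulls in all four nodes and edges
  d <- diamond_hierarchy()
  md <- node_metrics(coded_dataset(c(D = 7)), d, include_self = TRUE)
  vd <- build_summary_view(d, md, codeviews:::new_selection("D", list()))
  expect_equal(vd$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(vd$edges), 4L)

  expect_error(build_summary_view(fx$h, fx$m,
                                  codeviews:::new_selection("Z", list())),
               "not in hierarchy")
})

test_that("closure and induced edges verify against set-filter oracles on random pairs", {
  for (seed in 1:100) {
    case <- random_case(seed, n_nodes = 25L)
    m <- node_metrics(case$ds, case$h, include_self = TRUE)
    set.seed(seed + 5000L)
    picked <- sample(case$h$nodes, sample(1:5, 1L))
    v <- build_summary_view(case$h, m, codeviews:::new_selection(picked, list()))
    # upward closure: no view node has an out-of-view ancestor (oracle DFS)
    for (n in v$nodes) {
      expect_true(all(oracle_reach(case$h, n, "in") %in% v$nodes))
    }
    # induced edges: independent filter of the raw edge list
    e <- case$h$edges
    keep <- e$parent %in% v$nodes & e$child %in% v$nodes
    expect_equal(nrow(v$edges), sum(keep))
  }
})

test_that("view size is monotone in the selection", {
  for (seed in 1:10) {
    case <- random_case(seed, n_nodes = 25L)
    m <- node_metrics(case$ds, case$h, include_self = TRUE)
    set.seed(seed + 7000L)
    small <- sample(case$h$nodes, 2L)
    big <- union(small, sample(case$h$nodes, 4L))
    v_small <- build_summary_view(case$h, m, codeviews:::new_selection(small, list()))
    v_big <- build_summary_view(case$h, m, codeviews:::new_selection(big, list()))
    expect_true(all(v_small$nodes %in% v_big$nodes))
    expect_gte(length(v_big$nodes), length(v_small$nodes))
  }
})

test_that("colors run green (min) to red (max), channel-wise linear", {
  h <- term_hierarchy(c("A", "B", "C"))
  m <- node_metrics(coded_dataset(c(A = 0, B = 5, C = 10)), h,
                    include_self = TRUE)
  v <- assign_colors(build_summary_view(h, m, select_threshold(m, "CC", 0)),
                     key = "CC")
  cols <- stats::setNames(v$annotations$color, v$annotations$code)
  expect_equal(unname(cols["A"]), "#00FF00")
  expect_equal(unname(cols["C"]), "#FF0000")
  mid <- grDevices::col2rgb(cols["B"])[, 1L]
  expect_equal(unname(mid["red"]), 128)    # round(255 * 0.5)
  expect_equal(unname(mid["green"]), 128)
  expect_equal(unname(mid["blue"]), 0)

  # constant values map uniformly to green
  mc <- node_metrics(coded_dataset(c(A = 3, B = 3, C = 3)), h,
                     include_self = TRUE)
  vc <- assign_colors(build_summary_view(h, mc, select_threshold(mc, "CC", 0)))
  expect_true(all(vc$annotations$color == "#00FF00"))

  # log scale still maps the extremes to the endpoints
  vl <- assign_colors(build_summary_view(h, m, select_threshold(m, "CC", 0)),
                      key = "CC", scale = "log")
  colsl <- stats::setNames(vl$annotations$color, vl$annotations$code)
  expect_equal(unname(colsl["A"]), "#00FF00")
  expect_equal(unname(colsl["C"]), "#FF0000")
})

test_that("DOT export is valid, complete, and parse-back recoverable", {
  fx <- view_fixture()
  v <- assign_colors(build_summary_view(fx$h, fx$m,
                                        select_threshold(fx$m, "CC", 0)))
  txt <- export_dot(v)
  lines <- strsplit(txt, "\n")[[1L]]
  expect_equal(lines[1L], "digraph summary_view {")
  expect_equal(tail(lines, 1L), "}")
  expect_equal(sum(grepl("\\[label=", lines)), 3L)  # one statement per node
  expect_equal(sum(grepl(" -> ", lines)), 2L)

  # parse-back oracle: recover node and edge sets from the DOT text
  node_ids <- sub('^\\s*"([^"]+)" \\[label=.*$', "\\1",
                  grep('^\\s*"[^"]+" \\[label=', lines, value = TRUE))
  expect_setequal(node_ids, v$nodes)
  edges <- regmatches(lines, regexec('"([^"]+)" -> "([^"]+)"', lines))
  edges <- Filter(function(x) length(x) == 3L, edges)
  expect_setequal(vapply(edges, function(x) paste(x[2L], x[3L]), ""),
                  paste(v$edges$parent, v$edges$child))

  # empty view still yields a syntactically closed digraph
  he <- term_hierarchy("A")
  me <- node_metrics(coded_dataset(c(A = 0)), he)
  ve <- build_summary_view(he, me, codeviews:::new_selection(character(0), list()))
  etxt <- export_dot(ve)
  expect_match(etxt, "digraph")
  expect_match(etxt, "\\}")
})

test_that("view CSV export is sorted, complete, and round-trippable", {
  fx <- view_fixture()
  v <- build_summary_view(fx$h, fx$m, select_threshold(fx$m, "CC", 0))
  txt <- export_view_csv(v)
  lines <- strsplit(txt, "\n")[[1L]]
  expect_equal(length(lines), 1L + 3L)
  tab <- utils::read.csv(text = txt)
  expect_equal(tab$code, v$nodes)
  expect_equal(tab$nc, v$annotations$nc)
  expect_equal(tab$cc, v$annotations$cc)
  expect_equal(tab$selected, v$annotations$selected)

  ve <- build_summary_view(fx$h, fx$m,
                           codeviews:::new_selection(character(0), list()))
  expect_equal(strsplit(export_view_csv(ve), "\n")[[1L]],
               "code,label,nc,cc,max_ratio,selected")
})

test_that("serialization is deterministic and GraphML mirrors the view", {
  for (seed in 1:5) {
    case <- random_case(seed, n_nodes = 20L)
    m <- node_metrics(case$ds, case$h, include_self = TRUE)
    v <- assign_colors(build_summary_view(case$h, m,
                                          select_top(m, "CC", "percent", 20)))
    expect_identical(export_dot(v), export_dot(v))
    expect_identical(export_graphml(v), export_graphml(v))
    expect_identical(export_view_csv(v), export_view_csv(v))

    xml <- xml2::read_xml(export_graphml(v))
    ns <- xml2::xml_ns(xml)
    nodes <- xml2::xml_find_all(xml, ".//d1:node", ns)
    expect_equal(length(nodes), length(v$nodes))
    expect_setequal(xml2::xml_attr(nodes, "id"), v$nodes)
    edges <- xml2::xml_find_all(xml, ".//d1:edge", ns)
    expect_equal(length(edges), nrow(v$edges))
  }
})

test_that("comparison views carry scores and signed deltas in tooltips", {
  h <- chain_hierarchy(c("R", "A", "B"))
  rec <- compare_datasets(coded_dataset(c(A = 30, B = 70)),
                          coded_dataset(c(A = 70, B = 30)), h,
                          include_self = TRUE)
  top <- top_differences(rec, "count", 2)
  v <- assign_colors(build_comparison_view(h, top), key = "score")
  expect_true(all(top$code %in% v$nodes))
  ann <- v$annotations
  expect_true(all(c("score") %in% names(ann)))
  b <- ann[ann$code == "B", ]
  expect_match(b$tooltip, "delta=\\+")
  expect_false(any(is.na(ann$color)))
})
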