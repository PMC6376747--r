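test_that("NC is the raw usage frequency, zero for uncoded ancestors", {
  h <- build_icd_hierarchy(c("E11.9", "I10"), "ICD10")
  ds <- coded_dataset(c(E11.9 = 4559, I10 = 3000), scheme = "ICD10")
  nc <- compute_nc(ds, h)
  expect_equal(unname(nc["E11.9"]), 4559)
  expect_equal(unname(nc["I10"]), 3000)
  expect_equal(unname(nc["E11"]), 0)
  expect_equal(sum(nc), event_count(ds))

  # empty dataset -> all-zero map
  empty <- coded_dataset(data.frame(code = character(0), frequency = numeric(0)),
                         scheme = "ICD10")
  expect_true(all(compute_nc(empty, h) == 0))

  bad <- coded_dataset(c(Z99 = 1), scheme = "ICD10")
  expect_error(compute_nc(bad, h), "Z99")
})

test_that("CC sums NC over distinct descendants", {
  ch <- chain_hierarchy()
  nc <- compute_nc(coded_dataset(c(B = 2, C = 3)), ch)
  cc <- compute_cc(nc, ch)
  expect_equal(unname(cc[c("A", "B", "C")]), c(5, 3, 0))

  # multi-path descendant counts once
  d <- diamond_hierarchy()
  ncd <- compute_nc(coded_dataset(c(D = 7)), d)
  ccd <- compute_cc(ncd, d)
  expect_equal(unname(ccd["A"]), 7)

  # single node: no descendants
  single <- term_hierarchy("X")
  nc1 <- c(X = 5)
  expect_equal(unname(compute_cc(nc1, single)), 0)
  expect_equal(unname(compute_cc(nc1, single, include_self = TRUE)), 5)

  # include_self = FALSE forces cc(leaf) = 0
  expect_equal(unname(cc["C"]), 0)
})

test_that("CC matches the naive DFS oracle on random DAGs, both conventions", {
  for (seed in 1:60) {
    case <- random_case(seed)
    nc <- compute_nc(case$ds, case$h)
    for (self in c(FALSE, TRUE)) {
      cc <- compute_cc(nc, case$h, include_self = self)
      expect_equal(unname(cc[case$h$nodes]),
                   unname(oracle_cc(case$h, nc, include_self = self)))
    }
  }
})

test_that("ratios are CC quotients in [0,1], absent when parent CC is zero", {
  cc <- c(A = 10, B = 5, C = 0)
  h <- chain_hierarchy()
  r <- compute_ratio(cc, h)
  expect_equal(r$ratio[r$child == "B"], 0.5)
  # parent B has cc 5 > 0, so edge (B,C) present with ratio 0
  expect_equal(r$ratio[r$child == "C"], 0)

  r0 <- compute_ratio(c(A = 0, B = 0, C = 0), h)
  expect_equal(nrow(r0), 0L)

  d <- diamond_hierarchy()
  ccd <- compute_cc(compute_nc(coded_dataset(c(D = 7)), d), d)
  rd <- compute_ratio(ccd, d)
  expect_equal(rd$ratio[rd$child == "B" & rd$parent == "A"], 1.0)
})

test_that("ratio bounds hold on the random suite and keys are hierarchy edges", {
  for (seed in 1:40) {
    case <- random_case(seed)
    m <- node_metrics(case$ds, case$h)
    r <- m$ratio
    expect_true(all(r$ratio >= 0 & r$ratio <= 1))
    ekeys <- paste(case$h$edges$parent, case$h$edges$child)
    expect_true(all(paste(r$parent, r$child) %in% ekeys))
    # key present iff parent cc > 0
    cc <- m$cc
    expect_equal(sum(cc[case$h$edges$parent] > 0), nrow(r))
  }
})

test_that("hierarchy monotonicity: child CC never exceeds parent CC (proper descendants)", {
  for (seed in 1:25) {
    case <- random_case(seed)
    m <- node_metrics(case$ds, case$h)
    e <- case$h$edges
    expect_true(all(m$cc[e$child] <= m$cc[e$parent]))
  }
})

test_that("top-node selection ranks the nonzero pool with deterministic ties", {
  h <- term_hierarchy(c("A", "B", "C", "Z"))
  m <- node_metrics(coded_dataset(c(A = 5, B = 3, C = 1)), h,
                    include_self = TRUE)
  expect_equal(select_top(m, "CC", "count", 2)$codes, c("A", "B"))
  # percent 100 -> whole nonzero pool; zero-count Z never enters
  expect_equal(select_top(m, "CC", "percent", 100)$codes, c("A", "B", "C"))
  # count beyond pool size is capped
  expect_equal(length(select_top(m, "CC", "count", 50)$codes), 3L)
  expect_error(select_top(m, "CC", "count", 0), "positive")
  expect_error(select_top(m, "CC", "percent", 150), "<= 100")

  # ceil rule: 5% of a 40-node pool -> 2
  h40 <- term_hierarchy(sprintf("K%02d", 1:40))
  m40 <- node_metrics(coded_dataset(stats::setNames(1:40, h40$nodes)), h40,
                      include_self = TRUE)
  expect_equal(length(select_top(m40, "NC", "percent", 5)$codes), 2L)

  # deterministic tie-break: equal metrics rank lexicographically
  ht <- term_hierarchy(c("B", "A", "C"))
  mt <- node_metrics(coded_dataset(c(A = 2, B = 2, C = 2)), ht,
                     include_self = TRUE)
  s1 <- select_top(mt, "NC", "count", 2)
  s2 <- select_top(mt, "NC", "count", 2)
  expect_identical(s1$codes, c("A", "B"))
  expect_identical(s1, s2)
})

test_that("threshold selection is inclusive and monotone", {
  h <- term_hierarchy(c("A", "B", "C"))
  m <- node_metrics(coded_dataset(c(A = 5, B = 3, C = 1)), h,
                    include_self = TRUE)
  expect_equal(select_threshold(m, "NC", 3)$codes, c("A", "B"))
  expect_equal(length(select_threshold(m, "NC", 0)$codes), 3L)
  expect_equal(length(select_threshold(m, "NC", 99)$codes), 0L)

  for (seed in 1:10) {
    case <- random_case(seed)
    m2 <- node_metrics(case$ds, case$h, include_self = TRUE)
    ts <- sort(sample(0:max(m2$cc), 4L))
    sets <- lapply(ts, function(t) select_threshold(m2, "CC", t)$codes)
    for (i in seq_len(length(sets) - 1L)) {
      expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
    }
  }
})

test_that("ratio selection uses the any-parent rule", {
  # poly-hierarchy: D under both B and C, with ratios 1.0 (via B, its
  # whole class) and 0.1 (via C, swamped by sibling E)
  h <- load_edge_list(data.frame(parent = c("A", "A", "B", "C", "C"),
                                 child = c("B", "C", "D", "D", "E")))
  m <- node_metrics(coded_dataset(c(D = 9, E = 81)), h, include_self = TRUE)
  r <- m$ratio
  expect_equal(sort(r$ratio[r$child == "D"]), c(0.1, 1.0))
  sel <- select_ratio(m, 0.5)
  expect_true("D" %in% sel$codes)  # qualifies through B alone
  expect_false("B" %in% sel$codes) # 9/99 via A stays below threshold

  expect_error(select_ratio(m, 1.5), "\\[0, 1\\]")

  # threshold 0 selects every child under a positive-CC parent
  sel0 <- select_ratio(m, 0)
  expect_setequal(sel0$codes, unique(m$ratio$child))

  # threshold 1: only children carrying the parent's entire class
  sel1 <- select_ratio(m, 1)
  expect_true("D" %in% sel1$codes)
})

test_that("selections combine by union and intersection", {
  s1 <- codeviews:::new_selection(c("A", "B"), list(key = "NC"))
  s2 <- codeviews:::new_selection(c("B", "C"), list(key = "RATIO"))
  expect_equal(combine_selections(list(s1, s2), "union")$codes, c("A", "B", "C"))
  expect_equal(combine_selections(list(s1, s2), "intersection")$codes, "B")
  expect_equal(combine_selections(list(s1))$codes, s1$codes)
  expect_error(combine_selections(list()), "at least one")
})

test_that("preview summarizes the nonzero distribution and threshold ladder", {
  h <- term_hierarchy(c("A", "B", "C", "Z"))
  m <- node_metrics(coded_dataset(c(A = 5, B = 3, C = 1)), h,
                    include_self = TRUE)
  pv <- preview_distribution(m, "NC", thresholds = c(1, 4, 6))
  expect_equal(pv$values, c(5, 3, 1))
  expect_equal(unname(pv$quantiles["median"]), 3)
  expect_equal(pv$ladder$survivors, c(3L, 1L, 0L))
  expect_false(pv$no_nonzero)

  zero <- node_metrics(coded_dataset(c(A = 0)), term_hierarchy("A"))
  pv0 <- preview_distribution(zero, "NC")
  expect_true(pv0$no_nonzero)
  expect_equal(length(pv0$values), 0L)
})

test_that("metrics CSV export carries code,label,nc,cc,max_ratio,selected", {
  h <- chain_hierarchy()
  m <- node_metrics(coded_dataset(c(B = 2, C = 3)), h)
  sel <- select_threshold(m, "CC", 3)
  txt <- write_metrics_csv(m, selection = sel)
  lines <- strsplit(txt, "\n")[[1L]]
  expect_equal(lines[1L], "code,label,nc,cc,max_ratio,selected")
  expect_equal(length(lines), 4L)
  tab <- utils::read.csv(text = txt)
  expect_equal(tab$cc[tab$code == "A"], 5)
  expect_true(tab$selected[tab$code == "A"])
  expect_false(tab$selected[tab$code == "C"])
})
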