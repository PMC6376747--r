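# Systematic comparison of two coded data sets over a shared hierarchy:
# node-by-node CC against CC. Because the two data sets generally differ in
# total events, the effect measure is the difference of CC proportions
# (each CC divided by its own data set's event count); optionally each node
# gets a continuity-corrected 2x2 chi-square test (node events vs remaining
# events in each data set) with Benjamini-Hochberg adjustment.

#' Compare two coded data sets node by node
#'
#' Computes CC for both data sets over the shared hierarchy and emits one
#' record per node with a positive CC in either data set. Proportions are
#' normalized by each data set's own event count; `delta = prop_a - prop_b`
#' and `score = |delta|` rank the differences. Nodes absent from one data
#' set's support get CC 0 there, so one-sided signals remain visible.
#'
#' @param ds_a,ds_b `coded_dataset` objects with the same scheme as `h`.
#' @param h the shared `term_hierarchy`.
#' @param include_self CC convention, as in [compute_cc()].
#' @param with_tests add per-node chi-square statistics (`chi2`, `p`) and
#'   BH-adjusted `q` values across all tested nodes.
#' @return a data.frame of class `cc_comparison` with columns `code`,
#'   `cc_a`, `cc_b`, `prop_a`, `prop_b`, `delta`, `score`, and when
#'   requested `chi2`, `p`, `q`; sorted by code.
#' @export
compare_datasets <- function(ds_a, ds_b, h, include_self = FALSE,
                             with_tests = FALSE) {
  stopifnot(inherits(ds_a, "coded_dataset"), inherits(ds_b, "coded_dataset"),
            inherits(h, "term_hierarchy"))
  if (ds_a$scheme != h$scheme || ds_b$scheme != h$scheme) {
    cv_config_error(sprintf("scheme mismatch: data sets are %s/%s, hierarchy is %s",
                            ds_a$scheme, ds_b$scheme, h$scheme))
  }
  tot_a <- event_count(ds_a); tot_b <- event_count(ds_b)
  if (tot_a <= 0 || tot_b <= 0) {
    cv_validation_error("cannot compare a data set with zero events (proportions undefined)")
  }
  cc_a <- compute_cc(compute_nc(ds_a, h), h, include_self = include_self)
  cc_b <- compute_cc(compute_nc(ds_b, h), h, include_self = include_self)
  keep <- cc_a > 0 | cc_b > 0
  codes <- sort(h$nodes[keep])
  out <- data.frame(code = codes,
                    cc_a = as.numeric(cc_a[codes]), cc_b = as.numeric(cc_b[codes]),
                    stringsAsFactors = FALSE)
  out$prop_a <- out$cc_a / tot_a
  out$prop_b <- out$cc_b / tot_b
  out$delta <- out$prop_a - out$prop_b
  out$score <- abs(out$delta)
  if (with_tests) {
    tests <- lapply(seq_len(nrow(out)), function(i) {
      tab <- matrix(c(out$cc_a[i], tot_a - out$cc_a[i],
                      out$cc_b[i], tot_b - out$cc_b[i]), nrow = 2)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      c(chi2 = unname(ct$statistic), p = unname(ct$p.value))
    })
    out$chi2 <- vapply(tests, `[[`, numeric(1), "chi2")
    out$p <- vapply(tests, `[[`, numeric(1), "p")
    out$q <- stats::p.adjust(out$p, method = "BH")
  }
  rownames(out) <- NULL
  structure(out, class = c("cc_comparison", "data.frame"),
            include_self = include_self,
            totals = c(a = tot_a, b = tot_b),
            sources = c(a = ds_a$source_name, b = ds_b$source_name))
}

#' Keep the largest per-node differences
#'
#' Ranks comparison records by `score` descending (ties by code) and
#' truncates by the same k-rule as [select_top()]: the top `value` records
#' in count mode (capped at the number of records), or the top
#' `ceiling(value/100 * n)` in percent mode.
#'
#' @param records a `cc_comparison` data.frame.
#' @param mode `"count"` or `"percent"`.
#' @param value positive number (a percentage in percent mode).
#' @return the truncated `cc_comparison`.
#' @export
top_differences <- function(records, mode = c("count", "percent"), value) {
  mode <- match.arg(mode)
  stopifnot(inherits(records, "cc_comparison"))
  if (!is.numeric(value) || length(value) != 1L || value <= 0) {
    cv_config_error("top-differences value must be a positive number")
  }
  if (mode == "percent" && value > 100) {
    cv_config_error("percent value must be <= 100")
  }
  ord <- order(-records$score, records$code)
  k <- if (mode == "count") min(floor(value), nrow(records))
       else ceiling(value / 100 * nrow(records))
  out <- records[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("include_self", "totals", "sources")] <-
    attributes(records)[c("include_self", "totals", "sources")]
  out
}

#' Export a comparison to CSV
#'
#' Columns: code, label, cc_a, cc_b, prop_a, prop_b, delta, score, and
#' chi2/p/q when tests were computed.
#'
#' @param records a `cc_comparison`.
#' @param h the hierarchy the comparison was computed over (for labels).
#' @param path output path; `NULL` returns the CSV text.
#' @return `path` (or the CSV text), invisibly.
#' @export
write_comparison_csv <- function(records, h, path = NULL) {
  stopifnot(inherits(records, "cc_comparison"), inherits(h, "term_hierarchy"))
  has_tests <- "q" %in% names(records)
  hdr <- c("code", "label", "cc_a", "cc_b", "prop_a", "prop_b", "delta", "score")
  if (has_tests) hdr <- c(hdr, "chi2", "p", "q")
  body <- sprintf("%s,%s,%s,%s,%s,%s,%s,%s",
                  records$code, csv_field(unname(h$labels[records$code])),
                  format_num(records$cc_a), format_num(records$cc_b),
                  fmt_real(records$prop_a), fmt_real(records$prop_b),
                  fmt_real(records$delta), fmt_real(records$score))
  if (has_tests) {
    body <- sprintf("%s,%s,%s,%s", body, fmt_real(records$chi2),
                    fmt_real(records$p), fmt_real(records$q))
  }
  emit_text(c(paste(hdr, collapse = ","), body), path)
}

# fixed-width scientific-free real formatting for stable artifacts
fmt_real <- function(x) {
  out <- sprintf("%.8f", x)
  out[is.na(x)] <- ""
  out
}
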