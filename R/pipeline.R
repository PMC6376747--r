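# End-to-end workflow: validate -> preview -> analyze (select algorithm,
# tune thresholds) -> compare -> export. One-shot runs driven by a
# RunConfig; the CLI script (inst/cli/codeviews.R) is a thin wrapper that
# maps classed errors to exit codes (0 ok, 2 validation failure, 3 config
# error, 4 I/O error).

CV_ALGORITHMS <- c("nc", "cc", "ratio", "top_nc", "top_cc", "top_nc_pct",
                   "top_cc_pct", "nc_plus_ratio", "cc_plus_ratio", "compare")

#' Build a pipeline run configuration
#'
#' @param command one of `"validate"`, `"preview"`, `"analyze"`,
#'   `"compare"`, `"generate"`.
#' @param input path to the coded data set CSV (two columns:
#'   code, frequency).
#' @param input_b second data set for `compare`.
#' @param scheme terminology scheme of the inputs.
#' @param terminology optional path to a terminology file (generic
#'   edge-list TSV, or MeSH descriptor/tree-number TSV when
#'   `scheme = "MESH"`). For ICD schemes the hierarchy is induced from the
#'   data set's own codes when no file is given.
#' @param algorithm one of `"nc"`, `"cc"`, `"ratio"`, `"top_nc"`,
#'   `"top_cc"`, `"top_nc_pct"`, `"top_cc_pct"`, `"nc_plus_ratio"`,
#'   `"cc_plus_ratio"`, `"compare"`.
#' @param value primary threshold / count / percentage for the algorithm.
#' @param ratio_value ratio threshold for the combination algorithms
#'   (`nc_plus_ratio`, `cc_plus_ratio`) and default for `ratio`.
#' @param include_self CC convention (see [compute_cc()]).
#' @param with_tests add chi-square/BH statistics to comparisons.
#' @param patient_count declared patient count (size rule applies only
#'   when provided).
#' @param allow_small override the minimum-size acceptability rule.
#' @param out_dir output directory for artifacts.
#' @param seed RNG seed (used by `generate`).
#' @param n_nodes,n_events,max_children,poly_fraction,zipf_exponent
#'   generator settings for `generate` (see [generator_config()]).
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(command = c("analyze", "validate", "preview", "compare",
                                   "generate"),
                       input = NULL, input_b = NULL, scheme = "GENERIC",
                       terminology = NULL, algorithm = "top_cc_pct",
                       value = 5, ratio_value = 0.8, include_self = FALSE,
                       with_tests = FALSE, patient_count = NULL,
                       allow_small = FALSE, out_dir = ".", seed = 1L,
                       n_nodes = 60L, n_events = 2000L, max_children = 4L,
                       poly_fraction = 0, zipf_exponent = 1.2,
                       log_level = c("info", "quiet")) {
  command <- match.arg(command)
  log_level <- match.arg(log_level)
  scheme <- match.arg(scheme, CV_SCHEMES)
  if (!(algorithm %in% CV_ALGORITHMS)) {
    cv_config_error(sprintf("unknown algorithm '%s' (choose from: %s)",
                            algorithm, paste(CV_ALGORITHMS, collapse = ", ")))
  }
  structure(list(command = command, input = input, input_b = input_b,
                 scheme = scheme, terminology = terminology,
                 algorithm = algorithm, value = value,
                 ratio_value = ratio_value, include_self = include_self,
                 with_tests = with_tests, patient_count = patient_count,
                 allow_small = allow_small, out_dir = out_dir,
                 seed = as.integer(seed), n_nodes = n_nodes,
                 n_events = n_events, max_children = max_children,
                 poly_fraction = poly_fraction, zipf_exponent = zipf_exponent,
                 log_level = log_level),
            class = "run_config")
}

cv_log <- function(cfg, fmt, ...) {
  if (cfg$log_level != "quiet") message(sprintf(paste0("[codeviews] ", fmt), ...))
  invisible(NULL)
}

#' Run the analytic pipeline
#'
#' Executes the configured command and writes its artifacts into
#' `cfg$out_dir`:
#' \describe{
#'   \item{validate}{`validation_report.csv`, `profile.json`. Raises a
#'     validation error (CLI exit 2) when error records exist or the size
#'     rule fails without `allow_small`.}
#'   \item{preview}{the above plus `preview.json` (threshold ladder).}
#'   \item{analyze}{the above plus `metrics.csv`, `view.dot`,
#'     `view.graphml`, `view.csv` for the chosen algorithm.}
#'   \item{compare}{`comparison.csv`, `comparison_view.dot/.graphml/.csv`.}
#'   \item{generate}{`hierarchy.tsv`, `dataset.csv` from the synthetic
#'     generator.}
#' }
#'
#' @param cfg a `run_config`.
#' @return list with `status` (0 on success) and `files` (paths written),
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(cfg$out_dir, name)

  if (cfg$command == "generate") {
    gcfg <- generator_config(n_nodes = cfg$n_nodes, max_children = cfg$max_children,
                             poly_fraction = cfg$poly_fraction,
                             n_events = cfg$n_events,
                             zipf_exponent = cfg$zipf_exponent, seed = cfg$seed)
    cv_log(cfg, "generate: n_nodes=%d n_events=%d seed=%d",
           gcfg$n_nodes, gcfg$n_events, gcfg$seed)
    h <- generate_hierarchy(gcfg)
    ds <- generate_dataset(h, gcfg)
    files <- c(write_edge_list_tsv(h, out("hierarchy.tsv")),
               write_dataset_csv(ds, out("dataset.csv")))
    return(invisible(list(status = 0L, files = files)))
  }

  if (is.null(cfg$input)) cv_config_error("an input data set is required")
  loaded <- read_dataset_csv(cfg$input, scheme = cfg$scheme,
                             patient_count = cfg$patient_count)
  ds <- loaded$dataset
  cv_log(cfg, "loaded %s: %d rows, %s events (%d parse issues)", cfg$input,
         nrow(ds$table), format_num(event_count(ds)), nrow(loaded$issues))

  h <- load_terminology(cfg, ds)
  report <- validate_dataset(ds, h)
  files <- c(files, write_error_records_csv(report, out("validation_report.csv")))
  jsonlite::write_json(report$profile, out("profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, out("profile.json"))
  cv_log(cfg, "validation: %d error record(s), size_ok=%s",
         nrow(report$error_records), report$size_ok)
  check_acceptable(cfg, report, loaded$issues)

  if (cfg$command == "validate") return(invisible(list(status = 0L, files = files)))

  metrics <- node_metrics(ds, h, include_self = cfg$include_self)

  if (cfg$command == "preview") {
    key <- if (grepl("nc", cfg$algorithm) && !grepl("^cc", cfg$algorithm)) "NC" else "CC"
    pv <- preview_distribution(metrics, key)
    jsonlite::write_json(list(key = pv$key, quantiles = as.list(pv$quantiles),
                              ladder = pv$ladder, no_nonzero = pv$no_nonzero),
                         out("preview.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, out("preview.json"))
    cv_log(cfg, "preview: %d nonzero %s values", length(pv$values), key)
    return(invisible(list(status = 0L, files = files)))
  }

  if (cfg$command == "compare" || cfg$algorithm == "compare") {
    if (is.null(cfg$input_b)) cv_config_error("compare requires a second input (input_b)")
    loaded_b <- read_dataset_csv(cfg$input_b, scheme = cfg$scheme)
    ds_b <- loaded_b$dataset
    hb <- load_terminology(cfg, ds, ds_b)
    rec <- compare_datasets(ds, ds_b, hb, include_self = cfg$include_self,
                            with_tests = cfg$with_tests)
    top <- top_differences(rec, mode = "count", value = max(1, floor(cfg$value)))
    files <- c(files, write_comparison_csv(rec, hb, out("comparison.csv")))
    cview <- assign_colors(build_comparison_view(hb, top), key = "score")
    files <- c(files,
               export_dot(cview, out("comparison_view.dot")),
               export_graphml(cview, out("comparison_view.graphml")),
               export_view_csv(cview, out("comparison_view.csv")))
    cv_log(cfg, "compare: %d records, top %d retained", nrow(rec), nrow(top))
    return(invisible(list(status = 0L, files = files)))
  }

  sel <- selection_for(cfg, metrics)
  files <- c(files, write_metrics_csv(metrics, out("metrics.csv"), selection = sel))
  view <- assign_colors(
    build_summary_view(h, metrics, sel,
                       title = sprintf("%s view (%s)", cfg$algorithm,
                                       basename(cfg$input))),
    key = if (grepl("^nc|top_nc", cfg$algorithm)) "NC" else "CC")
  files <- c(files,
             export_dot(view, out("view.dot")),
             export_graphml(view, out("view.graphml")),
             export_view_csv(view, out("view.csv")))
  cv_log(cfg, "analyze[%s]: %d selected, view of %d nodes", cfg$algorithm,
         length(sel$codes), length(view$nodes))
  invisible(list(status = 0L, files = files))
}

load_terminology <- function(cfg, ds, ds_b = NULL) {
  if (!is.null(cfg$terminology)) {
    if (cfg$scheme == "MESH") read_mesh_tsv(cfg$terminology)
    else read_edge_list_tsv(cfg$terminology, scheme = cfg$scheme)
  } else if (cfg$scheme %in% c("ICD9", "ICD10")) {
    codes <- names(dataset_entries(ds))
    if (!is.null(ds_b)) codes <- union(codes, names(dataset_entries(ds_b)))
    build_icd_hierarchy(codes, cfg$scheme)
  } else {
    cv_config_error(sprintf(
      "scheme %s requires a terminology file (--terminology)", cfg$scheme))
  }
}

check_acceptable <- function(cfg, report, issues) {
  problems <- character(0)
  if (nrow(issues)) {
    problems <- c(problems, sprintf("%d unparseable row(s)", nrow(issues)))
  }
  if (nrow(report$error_records)) {
    problems <- c(problems, sprintf("%d error record(s) (revise or delete them)",
                                    nrow(report$error_records)))
  }
  if (!report$size_ok && !cfg$allow_small) {
    problems <- c(problems, report$size_messages)
  }
  if (length(problems)) {
    cv_validation_error(paste0("data set not acceptable: ",
                               paste(problems, collapse = "; ")))
  }
  invisible(TRUE)
}

selection_for <- function(cfg, metrics) {
  v <- cfg$value
  switch(cfg$algorithm,
    nc = select_threshold(metrics, "NC", v),
    cc = select_threshold(metrics, "CC", v),
    ratio = select_ratio(metrics, if (is.null(v) || v > 1) cfg$ratio_value else v),
    top_nc = select_top(metrics, "NC", "count", v),
    top_cc = select_top(metrics, "CC", "count", v),
    top_nc_pct = select_top(metrics, "NC", "percent", v),
    top_cc_pct = select_top(metrics, "CC", "percent", v),
    nc_plus_ratio = combine_selections(list(
      select_threshold(metrics, "NC", v),
      select_ratio(metrics, cfg$ratio_value)), "union"),
    cc_plus_ratio = combine_selections(list(
      select_threshold(metrics, "CC", v),
      select_ratio(metrics, cfg$ratio_value)), "union"),
    cv_config_error(sprintf("algorithm '%s' is not a selection algorithm",
                            cfg$algorithm)))
}
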