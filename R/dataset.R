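# Coded data sets: a table of (terminology code, usage frequency) rows with
# optional patient-count metadata, plus the validation / correction workflow.
# Minimum acceptable size: patient count >= 100 (when declared) and event
# count >= 1000; both bounds inclusive.

CV_MIN_PATIENTS <- 100L
CV_MIN_EVENTS <- 1000L

#' Construct a coded data set
#'
#' @param entries named numeric vector (names = codes, values = frequencies)
#'   or a data.frame with columns `code` and `frequency`. Row order is kept:
#'   when the same code appears twice, the first occurrence defines the
#'   entry and later ones are flagged by [validate_dataset()].
#' @param scheme terminology scheme tag.
#' @param patient_count optional declared patient count (metadata; a
#'   frequency table alone cannot determine it).
#' @param source_name label used in provenance fields.
#' @return an object of class `coded_dataset`.
#' @export
coded_dataset <- function(entries, scheme = "GENERIC", patient_count = NULL,
                          source_name = "") {
  scheme <- match.arg(scheme, CV_SCHEMES)
  if (is.data.frame(entries)) {
    tab <- data.frame(code = normalize_code(entries$code, scheme),
                      frequency = as.numeric(entries$frequency),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(code = normalize_code(names(entries), scheme),
                      frequency = as.numeric(entries),
                      stringsAsFactors = FALSE)
  }
  if (any(!nzchar(tab$code))) cv_config_error("empty code in data set")
  if (anyNA(tab$frequency) || any(tab$frequency != floor(tab$frequency))) {
    cv_config_error("frequencies must be integers")
  }
  tab$row <- seq_len(nrow(tab))
  if (!is.null(patient_count)) {
    patient_count <- as.integer(patient_count)
    if (is.na(patient_count) || patient_count <= 0L) {
      cv_config_error("patient_count must be a positive integer")
    }
  }
  structure(list(table = tab[c("row", "code", "frequency")], scheme = scheme,
                 patient_count = patient_count, source_name = source_name),
            class = "coded_dataset")
}

#' Entries map of a data set (first occurrence per code)
#' @param ds a `coded_dataset`.
#' @return named numeric vector, code -> frequency.
#' @export
dataset_entries <- function(ds) {
  stopifnot(inherits(ds, "coded_dataset"))
  tab <- ds$table[!duplicated(ds$table$code), , drop = FALSE]
  stats::setNames(tab$frequency, tab$code)
}

#' Total event count of a data set
#' @param ds a `coded_dataset`.
#' @return sum of the frequencies of its entries.
#' @export
event_count <- function(ds) sum(dataset_entries(ds))

#' Read a coded data set from a two-column CSV
#'
#' The expected format is two comma-separated columns: terminology code and
#' usage frequency. Malformed rows (wrong field count, non-integer
#' frequency, empty code) are retained as parse issues, never silently
#' dropped. A header is auto-detected when the first row's second field is
#' not an integer; pass `has_header` to force it.
#'
#' @param path file path.
#' @param scheme terminology scheme of the codes.
#' @param has_header `NA` (auto-detect), `TRUE`, or `FALSE`.
#' @param patient_count optional declared patient count.
#' @return list with elements `dataset` (a `coded_dataset`) and `issues`
#'   (data.frame: row, raw_code, raw_frequency, reason).
#' @export
read_dataset_csv <- function(path, scheme = "GENERIC", has_header = NA,
                             patient_count = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  issues <- data.frame(row = integer(0), raw_code = character(0),
                       raw_frequency = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  add_issue <- function(row, code, freq, reason) {
    rbind(issues, data.frame(row = row, raw_code = code, raw_frequency = freq,
                             reason = reason, stringsAsFactors = FALSE))
  }
  codes <- character(0); freqs <- numeric(0)
  if (length(lines)) {
    fields <- strsplit(lines, ",", fixed = TRUE)
    start <- 1L
    if (is.na(has_header)) {
      f1 <- fields[[1L]]
      has_header <- length(f1) >= 2L && !grepl("^\\s*-?[0-9]+\\s*$", f1[[2L]])
    }
    if (isTRUE(has_header)) start <- 2L
    for (i in seq_along(fields)) {
      if (i < start) next
      f <- fields[[i]]
      if (length(f) != 2L) {
        issues <- add_issue(i, paste(f, collapse = ","), "",
                            sprintf("expected 2 fields, found %d", length(f)))
        next
      }
      code <- normalize_code(f[[1L]], scheme)
      raw_freq <- trimws(f[[2L]])
      if (!nzchar(code)) {
        issues <- add_issue(i, f[[1L]], raw_freq, "empty code")
        next
      }
      if (!grepl("^-?[0-9]+$", raw_freq)) {
        issues <- add_issue(i, code, raw_freq, "non-integer frequency")
        next
      }
      codes <- c(codes, code)
      freqs <- c(freqs, as.numeric(raw_freq))
    }
  }
  ds <- coded_dataset(data.frame(code = codes, frequency = freqs,
                                 stringsAsFactors = FALSE),
                      scheme = scheme, patient_count = patient_count,
                      source_name = basename(path))
  list(dataset = ds, issues = issues)
}

#' Write a coded data set to CSV
#' @param ds a `coded_dataset`.
#' @param path output path.
#' @param header write a `code,frequency` header row (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path, header = TRUE) {
  stopifnot(inherits(ds, "coded_dataset"))
  lines <- sprintf("%s,%s", ds$table$code, format_num(ds$table$frequency))
  if (header) lines <- c("code,frequency", lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Validate a coded data set
#'
#' Produces a report of error records (negative frequency; duplicate code,
#' i.e. any occurrence after the first; code absent from the supplied
#' hierarchy), checks the minimum-size acceptability rules (patient count
#' >= 100 when declared, event count >= 1000, both inclusive), and computes
#' the summary profile. Every rejected row carries exactly one primary
#' reason, checked in the order above.
#'
#' @param ds a `coded_dataset`.
#' @param h optional `term_hierarchy` to check code membership against.
#' @return an object of class `validation_report` with fields
#'   `error_records` (data.frame row/code/frequency/reason), `size_ok`,
#'   `size_messages`, and `profile`.
#' @export
validate_dataset <- function(ds, h = NULL) {
  stopifnot(inherits(ds, "coded_dataset"))
  tab <- ds$table
  reason <- rep(NA_character_, nrow(tab))
  reason[tab$frequency < 0] <- "negative frequency"
  dup <- duplicated(tab$code)
  reason[is.na(reason) & dup] <- "duplicate code"
  if (!is.null(h)) {
    stopifnot(inherits(h, "term_hierarchy"))
    reason[is.na(reason) & !(tab$code %in% h$nodes)] <- "unknown code"
  }
  err <- tab[!is.na(reason), , drop = FALSE]
  err$reason <- reason[!is.na(reason)]
  rownames(err) <- NULL

  ev <- event_count(ds)
  size_messages <- character(0)
  if (!is.null(ds$patient_count) && ds$patient_count < CV_MIN_PATIENTS) {
    size_messages <- c(size_messages, sprintf(
      "patient count %d is below the minimum of %d", ds$patient_count, CV_MIN_PATIENTS))
  }
  if (ev < CV_MIN_EVENTS) {
    size_messages <- c(size_messages, sprintf(
      "event count %s is below the minimum of %d", format_num(ev), CV_MIN_EVENTS))
  }
  entries <- dataset_entries(ds)
  prof <- list(
    distinct_codes = length(entries),
    event_count = ev,
    min_frequency = if (length(entries)) min(entries) else NA_real_,
    max_frequency = if (length(entries)) max(entries) else NA_real_,
    median_frequency = if (length(entries)) stats::median(entries) else NA_real_,
    unknown_codes = if (is.null(h)) NA_integer_ else sum(err$reason == "unknown code")
  )
  structure(list(error_records = err, size_ok = length(size_messages) == 0L,
                 size_messages = size_messages, profile = prof),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error record(s); size %s\n",
              nrow(x$error_records), if (x$size_ok) "OK" else "NOT acceptable"))
  for (m in x$size_messages) cat("  -", m, "\n")
  p <- x$profile
  cat(sprintf("  %d distinct codes, %s events (freq min/median/max: %s/%s/%s)\n",
              p$distinct_codes, format_num(p$event_count),
              format_num(p$min_frequency), format_num(p$median_frequency),
              format_num(p$max_frequency)))
  invisible(x)
}

#' Apply revise/delete corrections to error records
#'
#' Each action targets one error record of `report` by its `row` index and
#' either deletes that row or revises its code and/or frequency.
#' Re-validating the result leaves no error record for the acted-on rows
#' (unless a revision introduces a new problem).
#'
#' @param ds the `coded_dataset` the report was computed from.
#' @param report its `validation_report`.
#' @param actions list of `list(row =, action = "delete")` or
#'   `list(row =, action = "revise", code =, frequency =)` elements
#'   (`code`/`frequency` may be omitted to keep the current value).
#' @return a new `coded_dataset`.
#' @export
apply_corrections <- function(ds, report, actions) {
  stopifnot(inherits(ds, "coded_dataset"), inherits(report, "validation_report"))
  tab <- ds$table
  drop <- logical(nrow(tab))
  for (a in actions) {
    if (is.null(a$row) || !(a$row %in% report$error_records$row)) {
      cv_config_error(sprintf("action references row %s, which is not an error record",
                              a$row %||% "<missing>"))
    }
    i <- match(a$row, tab$row)
    act <- match.arg(a$action, c("delete", "revise"))
    if (act == "delete") {
      drop[i] <- TRUE
    } else {
      if (!is.null(a$code)) tab$code[i] <- normalize_code(a$code, ds$scheme)
      if (!is.null(a$frequency)) tab$frequency[i] <- as.numeric(a$frequency)
    }
  }
  tab <- tab[!drop, , drop = FALSE]
  coded_dataset(tab[c("code", "frequency")], scheme = ds$scheme,
                patient_count = ds$patient_count, source_name = ds$source_name)
}

#' Summary profile of a data set
#' @param ds a `coded_dataset`.
#' @return list: distinct code count, event count, min/max/median frequency
#'   (`NA` on an empty data set).
#' @export
dataset_profile <- function(ds) validate_dataset(ds)$profile

#' @export
print.coded_dataset <- function(x, ...) {
  cat(sprintf("<coded_dataset> scheme=%s '%s': %d rows, %d distinct codes, %s events%s\n",
              x$scheme, x$source_name, nrow(x$table),
              length(dataset_entries(x)), format_num(event_count(x)),
              if (is.null(x$patient_count)) ""
              else sprintf(", %d patients", x$patient_count)))
  invisible(x)
}

# plain decimal formatting, no scientific notation, no trailing zeros
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v)) sprintf("%d", as.integer(v))
    else sub("0+$", "", sprintf("%.6f", v))
  }, "")
}

#' Export validation error records to CSV
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_error_records_csv <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  err <- report$error_records
  lines <- c("row,code,frequency,reason",
             sprintf("%d,%s,%s,%s", err$row, err$code,
                     format_num(err$frequency), err$reason))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
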