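# Code normalization and syntax rules per terminology scheme.

CV_SCHEMES <- c("ICD9", "ICD10", "MESH", "GENERIC")

#' Normalize terminology codes for a scheme
#'
#' ICD codes are upper-cased with surrounding whitespace stripped and the
#' internal dot preserved; MeSH descriptor identifiers and generic codes keep
#' their case, with whitespace stripped.
#'
#' @param codes character vector of raw code tokens.
#' @param scheme one of `"ICD9"`, `"ICD10"`, `"MESH"`, `"GENERIC"`.
#' @return character vector of normalized codes.
#' @export
normalize_code <- function(codes, scheme = "GENERIC") {
  scheme <- match.arg(scheme, CV_SCHEMES)
  out <- trimws(as.character(codes))
  if (scheme %in% c("ICD9", "ICD10")) out <- toupper(out)
  out
}

# Syntax of a single code token, per scheme.
#   ICD-9-CM: 3-5 digits with an optional dot after the 3rd (001-999.99),
#             or E codes (E000-E999.9), or V codes (V01-V91.99).
#   ICD-10-CM: letter + digit + alnum, optional dot then 1-4 alnum.
icd_valid <- function(codes, scheme) {
  scheme <- match.arg(scheme, c("ICD9", "ICD10"))
  if (scheme == "ICD9") {
    grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", codes) |
      grepl("^E[0-9]{3}(\\.[0-9])?$", codes) |
      grepl("^V[0-9]{2}(\\.[0-9]{1,2})?$", codes)
  } else {
    grepl("^[A-Z][0-9][0-9A-Z](\\.[0-9A-Z]{1,4})?$", codes)
  }
}

# Parent of an ICD code: its longest proper prefix that is itself a valid
# code of the scheme (a trailing dot is dropped as the prefix crosses it).
# Category-level codes have no valid proper prefix and are roots -> NA.
icd_parent <- function(code, scheme) {
  cur <- code
  repeat {
    cur <- substr(cur, 1L, nchar(cur) - 1L)
    if (nchar(cur) == 0L) return(NA_character_)
    if (substr(cur, nchar(cur), nchar(cur)) == ".") {
      cur <- substr(cur, 1L, nchar(cur) - 1L)
    }
    if (icd_valid(cur, scheme)) return(cur)
  }
}
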