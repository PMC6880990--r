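#' Normalize ICD-9 codes to dotted canonical form
#'
#' Billing extracts carry ICD-9 codes in two dialects: dotted (`"331.0"`) and
#' dotless (`"3310"`, the decimal point implied after the third character, or
#' the fourth for E-codes). Both normalize to one dotted canonical form so that
#' mapping tables and visit extracts from different sources agree.
#'
#' Normalization is idempotent: a code already in canonical form is returned
#' unchanged. Codes are upper-cased and whitespace-trimmed first. A bare
#' three-character root (`"311"`, `"V70"`) has no decimal part and is left as
#' is.
#'
#' @param code Character vector of raw ICD-9 codes.
#' @return Character vector of the same length in dotted canonical form.
#'   Malformed entries (empty, or containing characters other than digits,
#'   a leading V/E and one dot) are returned as `NA` with a warning.
#' @examples
#' icd9_normalize(c("3310", "331.0", "296.21", "311", "V700", "E8790"))
#' @export
icd9_normalize <- function(code) {
  x <- toupper(trimws(as.character(code)))
  x[x == ""] <- NA_character_
  ok <- grepl("^[VE]?[0-9]+(\\.[0-9]*)?$", x) & !is.na(x)
  has_dot <- grepl("\\.", x)
  root_len <- ifelse(startsWith(x, "E"), 4L, 3L)
  out <- x
  # dotless codes longer than the root get the implied dot re-inserted
  need <- ok & !has_dot & nchar(x) > root_len
  out[need] <- paste0(
    substr(x[need], 1L, root_len[need]),
    ".",
    substr(x[need], root_len[need] + 1L, nchar(x[need]))
  )
  # a trailing dot ("331.") is noise, not a decimal part
  out <- sub("\\.$", "", out)
  bad <- !ok & !is.na(x)
  if (any(bad)) {
    warning(sprintf(
      "%d malformed ICD-9 code(s) set to NA (e.g. %s)",
      sum(bad), paste(utils::head(unique(x[bad]), 3L), collapse = ", ")
    ), call. = FALSE)
    out[bad] <- NA_character_
  }
  out
}

#' @keywords internal
is_valid_phecode <- function(x) {
  grepl("^[0-9]+(\\.[0-9]+)?$", x)
}
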