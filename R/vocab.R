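#' Load an ICD-9 to phecode mapping table
#'
#' Reads a delimited mapping file with columns `icd9`, `phecode`,
#' `phecode_label` and optionally `exclude_range`, and returns a validated
#' `phecode_map` object. Each ICD-9 code maps to exactly one phecode
#' (many-to-one); the exclusion range names the phecodes whose carriers must
#' be removed from the control pool when the phecode is the index disease.
#'
#' `exclude_range` is a semicolon-separated list of dash-separated phecode
#' intervals, e.g. `"296-302.99"` or `"290-294.99;331-331.99"`. When the
#' column is absent or empty the exclusion set defaults to the phecode
#' itself: carriers of the index phenotype are never eligible controls.
#'
#' Malformed rows (unparseable ICD-9, missing phecode) are reported in the
#' `dropped` attribute and via a warning, never silently discarded.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `phecode_map`: list with `map` (tibble `icd9`, `phecode`,
#'   `label`) and `exclusions` (tibble `phecode`, `lo`, `hi`, one row per
#'   exclusion interval, always covering the phecode itself).
#' @seealso [write_phecode_map()], [map_visits()]
#' @export
load_phecode_map <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("icd9", "phecode", "phecode_label")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("phecode map is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"exclude_range" %in% names(raw)) raw$exclude_range <- NA_character_

  raw$icd9_norm <- suppressWarnings(icd9_normalize(raw$icd9))
  bad <- is.na(raw$icd9_norm) | is.na(raw$phecode) | !is_valid_phecode(raw$phecode)
  dropped <- raw[bad, c("icd9", "phecode")]
  if (nrow(dropped) > 0) {
    warning(sprintf("%d malformed row(s) dropped from phecode map", nrow(dropped)),
            call. = FALSE)
  }
  tbl <- raw[!bad, , drop = FALSE]

  dup <- tbl |>
    dplyr::distinct(.data$icd9_norm, .data$phecode) |>
    dplyr::count(.data$icd9_norm) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    stop("duplicate ICD-9 code(s) with conflicting phecodes: ",
         paste(utils::head(dup$icd9_norm, 5L), collapse = ", "), call. = FALSE)
  }

  map <- tbl |>
    dplyr::distinct(icd9 = .data$icd9_norm, phecode = .data$phecode,
                    label = .data$phecode_label)

  exclusions <- tbl |>
    dplyr::distinct(.data$phecode, .data$exclude_range) |>
    dplyr::group_by(.data$phecode) |>
    dplyr::summarise(
      exclude_range = paste(stats::na.omit(.data$exclude_range), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(ranges = purrr::map2(.data$phecode, .data$exclude_range,
                                       parse_exclude_range)) |>
    dplyr::select("phecode", "ranges") |>
    tidyr::unnest("ranges")

  out <- structure(
    list(map = map, exclusions = exclusions),
    class = "phecode_map"
  )
  attr(out, "dropped") <- tibble::as_tibble(dropped)
  out
}

# "lo-hi;lo-hi" -> tibble(lo, hi); always includes the phecode's own point range
parse_exclude_range <- function(phecode, spec) {
  own <- tibble::tibble(lo = as.numeric(phecode), hi = as.numeric(phecode))
  if (is.null(spec) || is.na(spec) || spec == "") return(own)
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  parts <- parts[parts != ""]
  pieces <- purrr::map(parts, function(p) {
    ends <- strsplit(p, "-", fixed = TRUE)[[1]]
    lo <- as.numeric(ends[[1]])
    hi <- if (length(ends) > 1L) as.numeric(ends[[2]]) else lo
    if (is.na(lo) || is.na(hi) || lo > hi) {
      stop("malformed exclude_range interval: ", p, call. = FALSE)
    }
    tibble::tibble(lo = lo, hi = hi)
  })
  dplyr::distinct(dplyr::bind_rows(own, pieces))
}

#' @export
print.phecode_map <- function(x, ...) {
  cat(sprintf("<phecode_map> %d ICD-9 codes -> %d phecodes\n",
              nrow(x$map), dplyr::n_distinct(x$map$phecode)))
  invisible(x)
}

#' Write a phecode map back to its canonical CSV format
#'
#' Round-trips with [load_phecode_map()]: reloading the written file yields an
#' identical `icd9 -> phecode` mapping and identical exclusion intervals.
#'
#' @param map A `phecode_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phecode_map <- function(map, path) {
  stopifnot(inherits(map, "phecode_map"))
  excl <- map$exclusions |>
    dplyr::group_by(.data$phecode) |>
    dplyr::summarise(
      exclude_range = paste(sprintf("%s-%s", format(.data$lo, trim = TRUE),
                                    format(.data$hi, trim = TRUE)), collapse = ";"),
      .groups = "drop"
    )
  out <- map$map |>
    dplyr::left_join(excl, by = "phecode") |>
    dplyr::select(icd9 = "icd9", phecode = "phecode",
                  phecode_label = "label", "exclude_range")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Phecodes whose exclusion intervals cover a phecode of interest
#'
#' Given the index disease's phecode, returns every phecode in the map falling
#' inside any of its exclusion intervals. Carriers of those phecodes are
#' removed from the control pool by [match_controls()].
#'
#' @param map A `phecode_map`.
#' @param phecode Index phecode (character scalar).
#' @return Character vector of excluded phecodes (always contains `phecode`).
#' @export
exclusion_phecodes <- function(map, phecode) {
  stopifnot(inherits(map, "phecode_map"))
  iv <- map$exclusions |> dplyr::filter(.data$phecode == !!phecode)
  if (nrow(iv) == 0) iv <- tibble::tibble(lo = as.numeric(phecode), hi = as.numeric(phecode))
  all_codes <- unique(map$map$phecode)
  num <- as.numeric(all_codes)
  hit <- purrr::map_lgl(num, function(v) any(v >= iv$lo & v <= iv$hi))
  union(phecode, all_codes[hit])
}

#' Translate visit-level ICD-9 codes into phecodes
#'
#' One output row is produced per input visit whose (normalized) ICD-9 code is
#' present in the map; visits with unmapped codes are counted, reported via a
#' message, and recorded in the `n_unmapped` attribute — never an error, since
#' real extracts always contain codes outside the map.
#'
#' @param visits Data frame with columns `subject_id`, `age_at_visit`, `icd9`.
#' @param map A `phecode_map`.
#' @return Tibble `subject_id`, `age_at_visit`, `phecode` with attribute
#'   `n_unmapped`. Row count plus `n_unmapped` equals `nrow(visits)`.
#' @export
map_visits <- function(visits, map) {
  stopifnot(inherits(map, "phecode_map"))
  visits <- tibble::as_tibble(visits)
  if (nrow(visits) == 0) {
    out <- tibble::tibble(subject_id = character(), age_at_visit = numeric(),
                          phecode = character())
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  norm <- suppressWarnings(icd9_normalize(visits$icd9))
  hit <- match(norm, map$map$icd9)
  n_unmapped <- sum(is.na(hit))
  out <- tibble::tibble(
    subject_id = as.character(visits$subject_id),
    age_at_visit = as.numeric(visits$age_at_visit),
    phecode = map$map$phecode[hit]
  )[!is.na(hit), ]
  if (n_unmapped > 0) {
    message(sprintf("map_visits: %d of %d visit(s) carried unmapped codes",
                    n_unmapped, nrow(visits)))
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Expand a phecode into literature search strings via concept identifiers
#'
#' Walks phecode -> ICD-9 children -> concept identifiers (CUIs) -> synonym
#' strings, the path used to build PubMed queries: each ICD-9 code under the
#' phecode is looked up in the `icd9,cui` table and every string attached to
#' any of those CUIs in the `cui,string` table is collected, lower-cased and
#' deduplicated.
#'
#' @param phecode Character scalar.
#' @param map A `phecode_map` (defines the phecode's ICD-9 children).
#' @param icd9_to_cui Data frame with columns `icd9`, `cui`.
#' @param cui_to_strings Data frame with columns `cui`, `string`.
#' @return A `concept_strings` object: list with `phecode`, `concept_ids`
#'   (character) and `strings` (lower-case, case-insensitively deduplicated
#'   character). Both are empty, with a warning, when the phecode has no
#'   ICD-9 children in the concept table.
#' @export
expand_concept_strings <- function(phecode, map, icd9_to_cui, cui_to_strings) {
  stopifnot(inherits(map, "phecode_map"))
  children <- map$map$icd9[map$map$phecode == phecode]
  icd9_to_cui <- tibble::as_tibble(icd9_to_cui)
  cui_to_strings <- tibble::as_tibble(cui_to_strings)
  icd9_to_cui$icd9 <- suppressWarnings(icd9_normalize(icd9_to_cui$icd9))
  cuis <- sort(unique(icd9_to_cui$cui[icd9_to_cui$icd9 %in% children]))
  if (length(children) == 0 || length(cuis) == 0) {
    warning(sprintf("phecode %s has no concept identifiers; empty search-string set",
                    phecode), call. = FALSE)
    return(structure(list(phecode = phecode, concept_ids = character(),
                          strings = character()), class = "concept_strings"))
  }
  strings <- tolower(cui_to_strings$string[cui_to_strings$cui %in% cuis])
  strings <- sort(unique(strings[!is.na(strings) & strings != ""]))
  structure(list(phecode = phecode, concept_ids = cuis, strings = strings),
            class = "concept_strings")
}

#' @export
print.concept_strings <- function(x, ...) {
  cat(sprintf("<concept_strings> phecode %s: %d CUI(s), %d string(s)\n",
              x$phecode, length(x$concept_ids), length(x$strings)))
  invisible(x)
}

#' Expand every phecode of a map into search strings
#'
#' Convenience wrapper over [expand_concept_strings()] for pipelines.
#'
#' @inheritParams expand_concept_strings
#' @param phecodes Phecodes to expand; defaults to every phecode in `map`.
#' @return Named list of string sets, one element per phecode.
#' @export
expand_concept_table <- function(map, icd9_to_cui, cui_to_strings,
                                 phecodes = NULL) {
  if (is.null(phecodes)) phecodes <- sort(unique(map$map$phecode))
  out <- purrr::map(phecodes, function(p) {
    suppressWarnings(expand_concept_strings(p, map, icd9_to_cui, cui_to_strings)$strings)
  })
  rlang::set_names(out, phecodes)
}
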