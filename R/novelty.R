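#' Literature-count providers
#'
#' A provider answers one question: how many papers mention a given set of
#' search strings (joined as an OR-group, optionally AND-ed with a second
#' group) in their title, abstract or keywords. Two implementations ship:
#'
#' * `lit_fixture_provider(path)` — reads a pinned counts file so analyses are
#'   reproducible even though the live literature grows daily. Format: a CSV
#'   with columns `phecode,pair_count`, preceded by a comment line
#'   `# disease_count: <N>` holding the denominator.
#' * `lit_entrez_provider(email, api_key)` — queries the NCBI E-utilities
#'   `esearch` endpoint live with fielded terms (`[tiab]`), at most 3
#'   requests per second. Requires network access; intended for real
#'   analyses, never used by the test-suite.
#'
#' Any function of signature `function(disease_strings, phecode_strings,
#' phecode)` returning a single count can serve as a provider (pass
#' `phecode_strings = NULL` for the disease-only denominator), which is how
#' recorded-response doubles are injected in tests.
#'
#' @param path Path to a fixture counts CSV.
#' @name lit_providers
#' @return A provider function.
#' @export
lit_fixture_provider <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*disease_count:\\s*([0-9]+)", first))[[1]]
  if (length(m) < 2) {
    stop("fixture counts file must start with '# disease_count: <N>'",
         call. = FALSE)
  }
  disease_count <- as.numeric(m[[2]])
  tbl <- readr::read_csv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(
                           phecode = readr::col_character(),
                           pair_count = readr::col_double()
                         ))
  counts <- rlang::set_names(tbl$pair_count, tbl$phecode)
  function(disease_strings, phecode_strings = NULL, phecode = NULL) {
    if (is.null(phecode_strings)) return(disease_count)
    if (is.null(phecode) || !phecode %in% names(counts)) {
      warning("fixture has no count for phecode ",
              phecode %||% "<missing>", "; using 0", call. = FALSE)
      return(0)
    }
    unname(counts[[phecode]])
  }
}

#' @param email Contact e-mail sent with every E-utilities request (NCBI
#'   policy).
#' @param api_key Optional NCBI API key.
#' @param max_retries Retries per query before a hard error.
#' @rdname lit_providers
#' @export
lit_entrez_provider <- function(email, api_key = NULL, max_retries = 3L) {
  force(email); force(api_key)
  last_request <- 0
  function(disease_strings, phecode_strings = NULL, phecode = NULL) {
    term <- build_pubmed_query(disease_strings, phecode_strings)
    url <- paste0(
      "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi",
      "?db=pubmed&rettype=count&retmode=json",
      "&term=", utils::URLencode(term, reserved = TRUE),
      "&email=", utils::URLencode(email, reserved = TRUE),
      if (!is.null(api_key)) paste0("&api_key=", api_key) else ""
    )
    for (attempt in seq_len(max_retries)) {
      wait <- 1 / 3 - (as.numeric(Sys.time()) - last_request)
      if (wait > 0) Sys.sleep(wait)
      last_request <<- as.numeric(Sys.time())
      res <- tryCatch(jsonlite::fromJSON(url), error = function(e) NULL)
      if (!is.null(res$esearchresult$count)) {
        return(as.numeric(res$esearchresult$count))
      }
    }
    stop("E-utilities query failed after ", max_retries, " attempts: ", term,
         call. = FALSE)
  }
}

#' Build a fielded PubMed query from string sets
#'
#' `(s1[tiab] OR s2[tiab] ...) AND (p1[tiab] OR ...)`: a paper counts when it
#' mentions any disease string and (if given) any phecode string in its
#' title, abstract or keywords.
#'
#' @param disease_strings,phecode_strings Character vectors of search strings;
#'   `phecode_strings = NULL` builds the disease-only denominator query.
#' @return Query string.
#' @export
build_pubmed_query <- function(disease_strings, phecode_strings = NULL) {
  stopifnot(length(disease_strings) > 0)
  grp <- function(s) {
    s <- sort(unique(tolower(trimws(s))))
    paste0("(", paste0('"', s, '"[tiab]', collapse = " OR "), ")")
  }
  q <- grp(disease_strings)
  if (!is.null(phecode_strings) && length(phecode_strings) > 0) {
    q <- paste(q, "AND", grp(phecode_strings))
  }
  q
}

#' Count literature co-mentions for each phecode-disease pairing
#'
#' Obtains, through `provider`, the number of papers mentioning the index
#' disease (the denominator) and — per phecode — the number mentioning both
#' the disease and the phecode's concept strings. Counts are cached in a JSON
#' file keyed by the normalized query, so a warm cache issues zero provider
#' calls; the cache survives across sessions and pins live results in time.
#'
#' @param disease_strings Character vector of search strings for the index
#'   disease (non-empty).
#' @param phecode_strings Named list: per phecode, its search strings (e.g.
#'   from [expand_concept_table()]).
#' @param provider A provider function; see [lit_providers].
#' @param cache Optional path to a JSON cache file.
#' @return Tibble `phecode`, `pair_count`, `disease_count`, `proportion`
#'   (pair/disease), with `disease_count` also in an attribute. Pair counts
#'   exceeding the disease count are an integrity error.
#' @export
fetch_counts <- function(disease_strings, phecode_strings, provider,
                         cache = NULL) {
  stopifnot(length(disease_strings) > 0)
  cache_env <- load_count_cache(cache)
  ask <- function(pstrings, phecode) {
    key <- build_pubmed_query(disease_strings, pstrings)
    if (!is.null(cache_env[[key]])) return(cache_env[[key]])
    val <- provider(disease_strings, pstrings, phecode)
    cache_env[[key]] <- val
    val
  }
  disease_count <- ask(NULL, NULL)
  if (disease_count <= 0) {
    stop("provider returned a non-positive disease count", call. = FALSE)
  }
  phecodes <- names(phecode_strings)
  pair <- purrr::map_dbl(phecodes, function(p) ask(phecode_strings[[p]], p))
  if (any(pair > disease_count)) {
    stop("pair count exceeds disease count for phecode(s): ",
         paste(phecodes[pair > disease_count], collapse = ", "), call. = FALSE)
  }
  save_count_cache(cache, cache_env)
  out <- tibble::tibble(
    phecode = phecodes,
    pair_count = pair,
    disease_count = disease_count,
    proportion = pair / disease_count
  )
  attr(out, "disease_count") <- disease_count
  out
}

load_count_cache <- function(path) {
  env <- new.env(parent = emptyenv())
  if (!is.null(path) && file.exists(path)) {
    stored <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in names(stored$counts)) env[[k]] <- stored$counts[[k]]
  }
  env
}

save_count_cache <- function(path, env) {
  if (is.null(path)) return(invisible(NULL))
  keys <- ls(env)
  jsonlite::write_json(
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         counts = rlang::set_names(lapply(keys, function(k) env[[k]]), keys)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Novelty score: one minus the empirical CDF of PubMed proportions
#'
#' Ranks how studied each phecode-disease pairing is relative to the other
#' pairings under consideration: `n_s = 1 - F(x)` where `F(x)` is the
#' self-inclusive empirical CDF, `F(x) = #\{proportions <= x\} / M`. The
#' most-studied pairing always scores exactly 0; ties share a value; higher
#' proportion never yields higher novelty.
#'
#' @param proportion Numeric vector of PubMed proportions (at least one).
#' @return Numeric vector of novelty scores in `[0, 1)`, same order as input.
#' @examples
#' novelty_score(c(0.5, 0.2, 0.1))  # 0, 1/3, 2/3
#' @export
novelty_score <- function(proportion) {
  stopifnot(length(proportion) >= 1, !anyNA(proportion))
  m <- length(proportion)
  vapply(proportion, function(x) 1 - sum(proportion <= x) / m, numeric(1))
}

#' Novelty Finding Index
#'
#' `NFI = PPV * n_s * 10`: reliability times relative novelty, scaled onto
#' `[0, 10]` so it is not mistaken for a probability. Values near 0 mark
#' findings that are well known (or unreliable); values near 10 mark reliable,
#' understudied findings.
#'
#' @param ppv Positive predictive values in `[0, 1]`.
#' @param n_s Novelty scores in `[0, 1]`.
#' @return NFI values in `[0, 10]`.
#' @export
nfi <- function(ppv, n_s) {
  stopifnot(all(is.na(ppv) | (ppv >= 0 & ppv <= 1)),
            all(is.na(n_s) | (n_s >= 0 & n_s <= 1)))
  ppv * n_s * 10
}

#' Attach literature novelty columns to screen results
#'
#' Joins per-phecode PubMed proportions, computes the novelty score over the
#' reference set, and composes the NFI for significant findings. The
#' reference set for the empirical CDF is, by default, every phecode with a
#' proportion available among the screened phecodes — the larger set
#' stabilizes the CDF; set `only_significant = TRUE` to rank among `p = 0`
#' findings only. NFI is computed only where the PPV is defined (significant
#' findings); other rows carry `NA`.
#'
#' @param results Output of [add_sgpv()].
#' @param counts Output of [fetch_counts()] (columns `phecode`, `proportion`).
#' @param only_significant Restrict the CDF reference set to significant
#'   findings? Default `FALSE`.
#' @return `results` with `proportion`, `n_s`, `nfi` columns added, sorted
#'   with significant findings first in decreasing NFI.
#' @export
add_novelty <- function(results, counts, only_significant = FALSE) {
  results <- tibble::as_tibble(results)
  results <- dplyr::left_join(
    results, dplyr::select(tibble::as_tibble(counts), "phecode", "proportion"),
    by = "phecode"
  )
  ref <- !is.na(results$proportion)
  if (only_significant) ref <- ref & !is.na(results$p_delta) & results$p_delta == 0
  results$n_s <- NA_real_
  if (any(ref)) {
    scores <- novelty_score(results$proportion[ref])
    results$n_s[ref] <- scores
  }
  results$nfi <- ifelse(
    !is.na(results$p_delta) & results$p_delta == 0 & !is.na(results$ppv),
    nfi(results$ppv, results$n_s), NA_real_
  )
  dplyr::arrange(results, dplyr::desc(!is.na(.data$nfi)),
                 dplyr::desc(.data$nfi), .data$phecode)
}
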