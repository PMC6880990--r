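#' Run the whole screening pipeline from one configuration
#'
#' Orchestrates, from a single YAML/JSON config (or equivalent list):
#' cohort input (files or the synthetic generator), visit censoring, ICD-9 to
#' phecode mapping, aggregation, the per-phecode logistic screen, the
#' second-generation p-value and PPV step, optional literature novelty, the
#' ranked results table, the odds-ratio plot and a run log recording every
#' effective setting and the subject/visit counts at each filter stage.
#' Deterministic given the config, its seed and a fixture count provider.
#'
#' Config keys (defaults in parentheses):
#' * `null_interval_or` — length-2 OR-scale null interval, required, `lo < hi`.
#' * `pi0` (0.5), `ci_level` (0.95), `min_carriers` (5), `measure`
#'   (`"binary"`), `seed` (1).
#' * `censor` — optional list `mode`, `lo`, `hi`.
#' * `simulate` — optional list passed to [sim_config()] (catalog defaults
#'   apply); otherwise `inputs` must give `subjects`, `visits`,
#'   `phecode_map` file paths.
#' * `novelty` — optional list: `counts_fixture` (path) or `provider = "live"`
#'   plus `email`/`api_key`, `disease_strings`, optional `concept_tables`
#'   (`icd9_cui`, `cui_strings` paths), `only_significant` (false).
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @param out_dir Output directory for `results.csv`, `or_plot.png` and
#'   `run_log.json`; `NULL` skips writing.
#' @return The results tibble (one row per screened phecode), invisibly when
#'   `out_dir` is given, with the output paths in attribute `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(cfg)
  null <- null_interval(cfg$null_interval_or)
  log <- list(
    package_version = as.character(utils::packageVersion("phescreen")),
    null_interval_or = cfg$null_interval_or,
    null_interval_log = c(null$lo, null$hi),
    pi0 = cfg$pi0, ci_level = cfg$ci_level,
    min_carriers = cfg$min_carriers, measure = cfg$measure,
    seed = cfg$seed, provider = cfg$novelty$provider %||% "none"
  )

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    if (!is.null(sim_args$catalog)) sim_args$catalog <- tibble::as_tibble(sim_args$catalog)
    if (!is.null(sim_args$planted)) sim_args$planted <- tibble::as_tibble(sim_args$planted)
    sc <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(sc)
    subjects <- cohort$subjects
    visits <- cohort$visits
    map <- synthetic_phecode_map(sc$catalog$phecode)
    log$source <- "synthetic"
  } else {
    subjects <- readr::read_csv(
      cfg$inputs$subjects, progress = FALSE, show_col_types = FALSE,
      col_types = readr::cols(subject_id = readr::col_character(),
                              sex = readr::col_character())
    )
    # codes must stay character: "331.0" is not the number 331
    visits <- readr::read_csv(
      cfg$inputs$visits, progress = FALSE, show_col_types = FALSE,
      col_types = readr::cols(subject_id = readr::col_character(),
                              icd9 = readr::col_character())
    )
    map <- load_phecode_map(cfg$inputs$phecode_map)
    log$source <- "files"
  }
  log$n_subjects <- nrow(subjects)
  log$n_visits_raw <- nrow(visits)

  if (!is.null(cfg$censor)) {
    visits <- censor_visits(visits, subjects, mode = cfg$censor$mode,
                            lo = cfg$censor$lo %||% 0,
                            hi = cfg$censor$hi %||% Inf)
  }
  log$n_visits_censored <- nrow(visits)

  mapped <- map_visits(visits, map)
  log$n_visits_mapped <- nrow(mapped)
  log$n_visits_unmapped <- attr(mapped, "n_unmapped")

  mat <- aggregate_phecodes(mapped, subjects, measure = cfg$measure)
  log$n_phecodes <- length(attr(mat, "phecodes"))

  results <- run_screen(mat, level = cfg$ci_level,
                        min_carriers = cfg$min_carriers) |>
    add_sgpv(null, pi0 = cfg$pi0)
  log$n_fitted <- sum(is.na(results$skip_reason))
  log$n_skipped <- sum(!is.na(results$skip_reason))
  log$n_significant <- sum(results$p_delta == 0, na.rm = TRUE)

  if (!is.null(cfg$novelty)) {
    results <- pipeline_novelty(results, cfg, map)
  } else {
    results$proportion <- NA_real_
    results$n_s <- NA_real_
    results$nfi <- NA_real_
  }
  results <- structure(results, null_interval = null,
                       class = c("phescreen_results", class(results)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(results = file.path(out_dir, "results.csv"),
               plot = file.path(out_dir, "or_plot.png"),
               log = file.path(out_dir, "run_log.json"))
    readr::write_csv(dplyr::mutate(results,
                                   classification = as.character(.data$classification)),
                     paths[["results"]], progress = FALSE)
    p <- render_or_plot(results, null)
    ggplot2::ggsave(paths[["plot"]], p, width = 8, height = 6, dpi = 150)
    jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    attr(results, "paths") <- paths
    return(invisible(results))
  }
  attr(results, "run_log") <- log
  results
}

pipeline_novelty <- function(results, cfg, map) {
  nv <- cfg$novelty
  provider <- if (identical(nv$provider, "live")) {
    lit_entrez_provider(email = nv$email, api_key = nv$api_key)
  } else {
    lit_fixture_provider(nv$counts_fixture)
  }
  phecodes <- results$phecode
  strings <- if (!is.null(nv$concept_tables)) {
    expand_concept_table(
      map,
      readr::read_csv(nv$concept_tables$icd9_cui, col_types = "cc",
                      progress = FALSE),
      readr::read_csv(nv$concept_tables$cui_strings, col_types = "cc",
                      progress = FALSE),
      phecodes = phecodes
    )
  } else {
    # without concept tables, query on the phecode label itself
    rlang::set_names(as.list(phecodes), phecodes)
  }
  counts <- suppressWarnings(
    fetch_counts(nv$disease_strings %||% "index disease", strings, provider,
                 cache = nv$cache)
  )
  add_novelty(results, counts, only_significant = isTRUE(nv$only_significant))
}

#' Validate a pipeline configuration, reporting every problem at once
#'
#' @param cfg Named list.
#' @return The config with defaults filled in; errors if invalid.
#' @keywords internal
validate_config <- function(cfg) {
  errs <- character()
  ni <- cfg$null_interval_or
  if (is.null(ni) || length(ni) != 2 || !is.numeric(unlist(ni))) {
    errs <- c(errs, "null_interval_or must be a length-2 numeric (OR scale)")
  } else {
    ni <- as.numeric(unlist(ni))
    if (!(ni[1] > 0 && ni[1] < ni[2])) {
      errs <- c(errs, sprintf("null_interval_or [%g, %g] must satisfy 0 < lo < hi",
                              ni[1], ni[2]))
    }
    cfg$null_interval_or <- ni
  }
  cfg$pi0 <- cfg$pi0 %||% 0.5
  if (cfg$pi0 < 0 || cfg$pi0 > 1) errs <- c(errs, "pi0 must lie in [0, 1]")
  cfg$ci_level <- cfg$ci_level %||% 0.95
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1) {
    errs <- c(errs, "ci_level must lie in (0, 1)")
  }
  cfg$min_carriers <- cfg$min_carriers %||% 5L
  cfg$measure <- cfg$measure %||% "binary"
  if (!cfg$measure %in% c("binary", "count", "duration")) {
    errs <- c(errs, "measure must be binary, count or duration")
  }
  cfg$seed <- cfg$seed %||% 1L
  if (!is.null(cfg$censor) &&
      !identical(cfg$censor$mode %in% c("age_interval", "left_censor",
                                        "right_censor"), TRUE)) {
    errs <- c(errs, "censor$mode must be age_interval, left_censor or right_censor")
  }
  if (is.null(cfg$simulate)) {
    for (k in c("subjects", "visits", "phecode_map")) {
      p <- cfg$inputs[[k]]
      if (is.null(p)) {
        errs <- c(errs, sprintf("inputs$%s is required when not simulating", k))
      } else if (!file.exists(p)) {
        errs <- c(errs, sprintf("inputs$%s file not found: %s", k, p))
      }
    }
  }
  if (!is.null(cfg$novelty) && !identical(cfg$novelty$provider, "live") &&
      is.null(cfg$novelty$counts_fixture)) {
    errs <- c(errs, "novelty requires counts_fixture unless provider is 'live'")
  }
  if (length(errs) > 0) {
    stop("invalid configuration:\n", paste("-", errs, collapse = "\n"),
         call. = FALSE)
  }
  cfg
}
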