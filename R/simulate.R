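#' Configuration for a synthetic visit-level cohort
#'
#' Bundles every knob of the generator: arm sizes, the phecode catalog with
#' per-phecode background (control-arm) prevalences, the planted effects,
#' demographic structure, the visit process and the censoring scenario.
#' Defaults emulate a mid-sized retrospective case-control extract: 1,000
#' subjects per arm, ages centred at 55 (sd 15, truncated to 0–100 years),
#' even sex ratio, and carriers accruing `1 + Poisson(1)` coded visits.
#'
#' @param n_cases,n_controls Subjects per arm.
#' @param catalog Tibble `phecode`, `prevalence` — background carriage
#'   probability in controls, each in `(0, 1)`.
#' @param planted Tibble `phecode`, `log_or` — planted case/control carriage
#'   log odds ratios; phecodes must be in the catalog. Unlisted phecodes have
#'   log OR 0.
#' @param age_mean,age_sd Subject age distribution (normal, truncated to
#'   `[0, 100]` years).
#' @param female_prob Probability a subject is female.
#' @param visit_lambda Poisson rate for extra visits per carrier (each carrier
#'   has `1 + Poisson(visit_lambda)` visits).
#' @param scenario Censoring scenario the visit ages are laid out for:
#'   `"age_interval"` (visit ages scattered around the subject's age),
#'   `"left_censor"` or `"right_censor"` (visit ages placed inside the
#'   diagnosis-anchored window).
#' @param window Length-2 window in years for left/right scenarios.
#' @param visit_spread Half-width in years of the visit-age scatter under
#'   `age_interval`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 1000L, n_controls = 1000L,
                       catalog = sim_catalog(),
                       planted = tibble::tibble(phecode = character(),
                                                log_or = numeric()),
                       age_mean = 55, age_sd = 15, female_prob = 0.5,
                       visit_lambda = 1, scenario = "age_interval",
                       window = c(0, 5), visit_spread = 2,
                       seed = 1L) {
  catalog <- tibble::as_tibble(catalog)
  planted <- tibble::as_tibble(planted)
  stopifnot(all(c("phecode", "prevalence") %in% names(catalog)),
            all(c("phecode", "log_or") %in% names(planted)))
  if (!all(catalog$prevalence > 0 & catalog$prevalence < 1)) {
    stop("catalog prevalences must lie in (0, 1)", call. = FALSE)
  }
  missing_p <- setdiff(planted$phecode, catalog$phecode)
  if (length(missing_p) > 0) {
    stop("planted phecode(s) absent from catalog: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  scenario <- match.arg(scenario, c("age_interval", "left_censor", "right_censor"))
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         catalog = catalog, planted = planted,
         age_mean = age_mean, age_sd = age_sd, female_prob = female_prob,
         visit_lambda = visit_lambda, scenario = scenario, window = window,
         visit_spread = visit_spread, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default synthetic phecode catalog
#'
#' @param n_phecodes Number of phecodes.
#' @param prevalence Background control-arm prevalence, recycled.
#' @return Tibble `phecode`, `prevalence`. Phecodes are three-digit roots
#'   with one decimal (e.g. `"101.1"`), disjoint from real clinical maps —
#'   they are synthetic stand-ins, not clinical phenotypes.
#' @export
sim_catalog <- function(n_phecodes = 20L, prevalence = 0.05) {
  tibble::tibble(
    phecode = sprintf("%d.1", 100L + seq_len(n_phecodes)),
    prevalence = rep_len(prevalence, n_phecodes)
  )
}

#' Build a synthetic ICD-9 to phecode map covering a set of phecodes
#'
#' Invents two ICD-9 children per phecode by appending a digit to the phecode
#' string (`"101.1"` gets children `"101.11"` and `"101.12"`), mirroring how
#' real phecodes group neighbouring ICD-9 codes. Exclusion sets default to
#' the phecode itself. Labels mark every entry as synthetic.
#'
#' @param phecodes Character vector of phecodes.
#' @return A `phecode_map`.
#' @export
synthetic_phecode_map <- function(phecodes) {
  phecodes <- sort(unique(phecodes))
  child <- function(p, d) if (grepl("\\.", p)) paste0(p, d) else paste0(p, ".", d)
  map <- tibble::tibble(
    phecode = rep(phecodes, each = 2L),
    icd9 = as.vector(vapply(phecodes, function(p) c(child(p, "1"), child(p, "2")),
                            character(2))),
    label = paste("synthetic phenotype", rep(phecodes, each = 2L))
  )
  structure(
    list(
      map = dplyr::select(map, "icd9", "phecode", "label"),
      exclusions = tibble::tibble(phecode = phecodes,
                                  lo = as.numeric(phecodes),
                                  hi = as.numeric(phecodes))
    ),
    class = "phecode_map"
  )
}

#' Generate a synthetic visit-level cohort with planted effects
#'
#' Carriage of each phecode is drawn independently per subject from a
#' logistic carriage model: controls carry with the catalog's background
#' prevalence `p0`, cases with probability `p1` such that the population
#' carriage odds ratio equals the planted value
#' (`odds1 = odds0 * exp(log_or)`). Each carrier receives `1 + Poisson`
#' coded visits whose ICD-9 codes are drawn from the phecode's children in
#' `map` and whose ages respect the censoring scenario, so the generated
#' files exercise the full mapping/censoring/aggregation path.
#'
#' @param config A [sim_config()].
#' @param map A `phecode_map` covering the catalog; defaults to
#'   [synthetic_phecode_map()] over the catalog's phecodes.
#' @return List with `subjects` (tibble `subject_id`, `sex`, `is_case`,
#'   `diagnosis_age`, `age`), `visits` (tibble `subject_id`, `age_at_visit`,
#'   `icd9`), and `truth` (tibble `phecode`, `true_log_or`).
#' @export
simulate_cohort <- function(config, map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(map)) map <- synthetic_phecode_map(config$catalog$phecode)
  uncovered <- setdiff(config$catalog$phecode, map$map$phecode)
  if (length(uncovered) > 0) {
    stop("map does not cover catalog phecode(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  with_preserved_seed(config$seed, {
    n <- config$n_cases + config$n_controls
    subjects <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      sex = ifelse(stats::runif(n) < config$female_prob, "female", "male"),
      is_case = rep(c(TRUE, FALSE), c(config$n_cases, config$n_controls)),
      diagnosis_age = trunc_norm(n, config$age_mean, config$age_sd, 0, 100)
    )
    subjects$age <- subjects$diagnosis_age

    truth <- config$catalog |>
      dplyr::left_join(config$planted, by = "phecode") |>
      dplyr::mutate(true_log_or = dplyr::coalesce(.data$log_or, 0)) |>
      dplyr::select("phecode", prevalence = "prevalence", "true_log_or")

    visit_rows <- vector("list", nrow(truth))
    for (j in seq_len(nrow(truth))) {
      p0 <- truth$prevalence[j]
      odds1 <- p0 / (1 - p0) * exp(truth$true_log_or[j])
      p1 <- odds1 / (1 + odds1)
      if (!is.finite(p1) || p1 <= 0 || p1 >= 1) {
        stop(sprintf("infeasible prevalence/effect for phecode %s (implied p = %g)",
                     truth$phecode[j], p1), call. = FALSE)
      }
      p_carry <- ifelse(subjects$is_case, p1, p0)
      carriers <- which(stats::runif(n) < p_carry)
      if (length(carriers) == 0) next
      n_visits <- 1L + stats::rpois(length(carriers), config$visit_lambda)
      idx <- rep(carriers, n_visits)
      ages <- visit_ages(subjects$diagnosis_age[idx], config)
      children <- map$map$icd9[map$map$phecode == truth$phecode[j]]
      visit_rows[[j]] <- tibble::tibble(
        subject_id = subjects$subject_id[idx],
        age_at_visit = ages,
        icd9 = children[1L + (seq_along(idx) - 1L) %% length(children)]
      )
    }
    visits <- dplyr::bind_rows(visit_rows) |>
      dplyr::arrange(.data$subject_id, .data$age_at_visit, .data$icd9)
    list(subjects = subjects,
         visits = visits,
         truth = dplyr::select(truth, "phecode", "true_log_or"))
  })
}

# normal draw truncated to [lo, hi] by inverse-CDF sampling
trunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# visit ages consistent with the censoring scenario, clamped to [0, 100]
visit_ages <- function(anchor, config) {
  n <- length(anchor)
  a <- switch(config$scenario,
    age_interval = anchor + stats::runif(n, -config$visit_spread,
                                         config$visit_spread),
    # window ages: closed at the diagnosis side, open at the far bound
    left_censor = anchor - stats::runif(n, config$window[1], config$window[2]),
    right_censor = anchor + stats::runif(n, config$window[1], config$window[2])
  )
  pmin(pmax(a, 0), 100)
}

#' Write a simulated cohort to the CSV dialects the loaders consume
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths
#'   (`subjects`, `visits`, `truth`), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    visits = file.path(dir, "visits.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(cohort$subjects, paths[["subjects"]], progress = FALSE)
  readr::write_csv(cohort$visits, paths[["visits"]], progress = FALSE)
  readr::write_csv(dplyr::rename(cohort$truth, true_log_or = "true_log_or"),
                   paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Run the full pipeline on a synthetic cohort and score recovery
#'
#' Simulates a cohort, pushes it through mapping, aggregation, the logistic
#' screen and the second-generation p-value step, then joins the truth table:
#' did planted-alternative phecodes (true log OR outside the null interval)
#' reach `p = 0`, and did null phecodes stay away from it?
#'
#' @param config A [sim_config()]; should plant at least one effect outside
#'   and one inside the null interval for an informative report.
#' @param null A [null_interval()].
#' @param pi0 Prior null probability for the PPV, default 0.5.
#' @param measure Aggregate measure, default `"binary"`.
#' @param min_carriers Carrier filter for the screen, default 5.
#' @return Tibble, one row per catalog phecode: `phecode`, `true_log_or`,
#'   `planted_alt` (truth outside the null), `p_delta`, `ppv`, `flagged`
#'   (`p_delta == 0`), `correct` (`flagged == planted_alt`).
#' @export
end_to_end_recovery <- function(config, null, pi0 = 0.5, measure = "binary",
                                min_carriers = 5L) {
  null <- as_null_interval(null)
  cohort <- simulate_cohort(config)
  mapped <- map_visits(cohort$visits, synthetic_phecode_map(config$catalog$phecode))
  mat <- aggregate_phecodes(mapped, cohort$subjects, measure = measure)
  res <- run_screen(mat, min_carriers = min_carriers) |>
    add_sgpv(null, pi0 = pi0)
  cohort$truth |>
    dplyr::left_join(dplyr::select(res, "phecode", "p_delta", "ppv"),
                     by = "phecode") |>
    dplyr::mutate(
      planted_alt = .data$true_log_or < null$lo | .data$true_log_or > null$hi,
      flagged = !is.na(.data$p_delta) & .data$p_delta == 0,
      correct = .data$flagged == .data$planted_alt
    )
}
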