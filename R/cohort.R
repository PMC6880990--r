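#' Restrict visits to the study's observation window
#'
#' Three censoring modes define which visits enter the analysis:
#'
#' * `age_interval`: keep visits with `lo <= age_at_visit < hi` (closed below,
#'   `hi` may be `Inf`). E.g. "all visits from age seven on" is `lo = 7`,
#'   `hi = Inf`.
#' * `left_censor`: visits in the window ending at the diagnosis — ages in
#'   `(d - hi, d - lo]` where `d` is the subject's diagnosis (or reference)
#'   age. "0–5 years before diagnosis" is `lo = 0`, `hi = 5`.
#' * `right_censor`: visits in the window starting at the diagnosis — ages in
#'   `[d + lo, d + hi)`. "0–5 years after diagnosis" is `lo = 0`, `hi = 5`.
#'
#' Windows are closed on the side nearest the diagnosis (the year of diagnosis
#' itself is included when `lo = 0`) and open at the far bound. Controls have
#' no diagnosis of their own: under left/right censoring each control's
#' `diagnosis_age` must hold the reference age inherited from its matched case
#' (see [match_controls()]).
#'
#' @param visits Data frame `subject_id`, `age_at_visit`, plus any other
#'   columns (e.g. `icd9` or `phecode`), which pass through untouched.
#' @param subjects Data frame `subject_id`, `is_case`, and `diagnosis_age`
#'   (required for `left_censor`/`right_censor` on every subject).
#' @param mode One of `"age_interval"`, `"left_censor"`, `"right_censor"`.
#' @param lo,hi Window bounds in years, `lo < hi`.
#' @return Tibble of the retained visit rows (never more rows than the input;
#'   applying the same window twice is a no-op).
#' @export
censor_visits <- function(visits, subjects, mode = c("age_interval", "left_censor",
                                                     "right_censor"),
                          lo = 0, hi = Inf) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(lo), is.numeric(hi))
  if (!(lo < hi)) stop("censor window requires lo < hi", call. = FALSE)
  visits <- tibble::as_tibble(visits)
  subjects <- tibble::as_tibble(subjects)

  if (mode == "age_interval") {
    return(visits[visits$age_at_visit >= lo & visits$age_at_visit < hi, ])
  }

  if (!"diagnosis_age" %in% names(subjects)) {
    stop(mode, " requires a diagnosis_age column on subjects", call. = FALSE)
  }
  d <- subjects$diagnosis_age[match(visits$subject_id, subjects$subject_id)]
  missing_d <- unique(visits$subject_id[is.na(d)])
  if (length(missing_d) > 0) {
    stop(mode, " requires diagnosis_age for every subject; missing for: ",
         paste(utils::head(missing_d, 5L), collapse = ", "),
         if (length(missing_d) > 5L) ", ..." else "", call. = FALSE)
  }
  a <- visits$age_at_visit
  keep <- if (mode == "left_censor") {
    a > d - hi & a <= d - lo
  } else {
    a >= d + lo & a < d + hi
  }
  visits[keep, ]
}

#' Select age- and sex-matched controls
#'
#' Greedy nearest-neighbour matching: cases are processed in descending order
#' of reference age (ties by subject id); for each case up to `ratio` controls
#' of identical sex and nearest `age` are drawn from the pool without
#' replacement. Pool members carrying any exclusion phecode for the index
#' disease are removed before matching — the standard control-hygiene step
#' that keeps near-cases out of the comparison group. A stratum that runs out
#' of eligible controls yields fewer matches with a warning, never silent
#' reuse.
#'
#' The draw is deterministic given `seed`: candidate order is fixed by a
#' seeded shuffle before the stable sort on age distance, so equidistant
#' candidates are broken reproducibly.
#'
#' @param cases,control_pool Data frames with columns `subject_id`, `sex`
#'   (`"male"`/`"female"`), `age` (reference age in years), and for cases
#'   optionally `diagnosis_age`. The pool must be disjoint from the cases.
#' @param ratio Controls per case, `>= 1`.
#' @param exclusions Character vector of phecodes; pool members carrying any
#'   of them (per `mapped_visits`) are ineligible.
#' @param mapped_visits Output of [map_visits()]; needed only when
#'   `exclusions` is non-empty.
#' @param seed Integer seed for the tie-breaking shuffle.
#' @return Tibble of matched controls: `subject_id`, `sex`, `age`,
#'   `case_id` (the matched case) and `diagnosis_age` inherited from the
#'   matched case when the case has one (risk-set alignment for left/right
#'   censoring).
#' @export
match_controls <- function(cases, control_pool, ratio = 1L,
                           exclusions = character(), mapped_visits = NULL,
                           seed = 1L) {
  cases <- tibble::as_tibble(cases)
  pool <- tibble::as_tibble(control_pool)
  stopifnot(ratio >= 1L)
  overlap <- intersect(cases$subject_id, pool$subject_id)
  if (length(overlap) > 0) {
    stop("control pool overlaps the case set: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(exclusions) > 0) {
    if (is.null(mapped_visits)) {
      stop("exclusions given but mapped_visits is NULL", call. = FALSE)
    }
    carriers <- unique(mapped_visits$subject_id[mapped_visits$phecode %in% exclusions])
    pool <- pool[!pool$subject_id %in% carriers, ]
  }

  if (!"diagnosis_age" %in% names(cases)) cases$diagnosis_age <- NA_real_
  ord <- order(-cases$age, cases$subject_id)
  cases <- cases[ord, ]

  # seeded shuffle fixes the order in which equidistant candidates are taken
  pool <- pool[order(pool$subject_id), ]
  pool <- with_preserved_seed(seed, pool[sample.int(nrow(pool)), ])
  available <- rep(TRUE, nrow(pool))

  picked <- vector("list", nrow(cases))
  shortfall <- 0L
  for (i in seq_len(nrow(cases))) {
    cand <- which(available & pool$sex == cases$sex[i])
    if (length(cand) == 0) {
      shortfall <- shortfall + ratio
      next
    }
    cand <- cand[order(abs(pool$age[cand] - cases$age[i]))]
    take <- utils::head(cand, ratio)
    if (length(take) < ratio) shortfall <- shortfall + (ratio - length(take))
    available[take] <- FALSE
    picked[[i]] <- tibble::tibble(
      subject_id = pool$subject_id[take],
      sex = pool$sex[take],
      age = pool$age[take],
      case_id = cases$subject_id[i],
      diagnosis_age = cases$diagnosis_age[i]
    )
  }
  out <- dplyr::bind_rows(picked)
  if (shortfall > 0) {
    warning(sprintf("control pool exhausted: %d fewer control(s) than requested",
                    shortfall), call. = FALSE)
  }
  out
}

# run code under a fixed seed without disturbing the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Aggregate mapped visits into a per-subject, per-phecode measure matrix
#'
#' Builds the design matrix for the per-phecode logistic screens: one row per
#' subject, one column per phecode holding the aggregate measure, plus the
#' covariates `age` (mean age over the subject's censored visits, falling back
#' to the subject table's `age`/`diagnosis_age` for subjects with no visits in
#' the window), `sex` (female = 1, male = 0; subjects of unknown sex are
#' dropped with a warning) and the case label `y`.
#'
#' Measures:
#' * `binary` — 1 if the phecode occurs at least once, else 0;
#' * `count` — number of visit rows carrying the phecode;
#' * `duration` — years between first and last occurrence (0 for a single
#'   occurrence).
#'
#' Subjects with no occurrence of a phecode get 0 under every measure;
#' subjects with no visits at all in the window are kept (all-zero row).
#'
#' @param mapped_visits Tibble `subject_id`, `age_at_visit`, `phecode`
#'   (already censored and mapped).
#' @param subjects Data frame `subject_id`, `sex`, `is_case`, optionally
#'   `age` and/or `diagnosis_age` (fallback reference age).
#' @param measure `"binary"`, `"count"` or `"duration"`.
#' @return An `aggregate_matrix`: tibble with `subject_id`, one numeric column
#'   per phecode, `age`, `sex`, `y`; the measure name is kept in the
#'   `measure` attribute.
#' @export
aggregate_phecodes <- function(mapped_visits, subjects,
                               measure = c("binary", "count", "duration")) {
  measure <- match.arg(measure)
  mv <- tibble::as_tibble(mapped_visits)
  subjects <- tibble::as_tibble(subjects)

  sex_code <- dplyr::case_match(tolower(as.character(subjects$sex)),
                                "female" ~ 1, "male" ~ 0, .default = NA)
  if (anyNA(sex_code)) {
    warning(sprintf("%d subject(s) of unknown sex excluded", sum(is.na(sex_code))),
            call. = FALSE)
  }
  subjects$sex_code <- sex_code
  subjects <- subjects[!is.na(sex_code), ]

  mv <- mv[mv$subject_id %in% subjects$subject_id, ]
  per <- mv |>
    dplyr::group_by(.data$subject_id, .data$phecode) |>
    dplyr::summarise(
      m = switch(measure,
        binary = 1,
        count = dplyr::n(),
        duration = max(.data$age_at_visit) - min(.data$age_at_visit)
      ),
      .groups = "drop"
    )
  phecodes <- sort(unique(per$phecode))

  wide <- per |>
    tidyr::pivot_wider(names_from = "phecode", values_from = "m",
                       values_fill = 0, names_sort = TRUE)

  mean_age <- mv |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(age = mean(.data$age_at_visit), .groups = "drop")

  fallback_age <- if ("age" %in% names(subjects)) {
    subjects$age
  } else if ("diagnosis_age" %in% names(subjects)) {
    subjects$diagnosis_age
  } else {
    rep(NA_real_, nrow(subjects))
  }

  out <- tibble::tibble(subject_id = as.character(subjects$subject_id)) |>
    dplyr::left_join(wide, by = "subject_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(phecodes), ~ tidyr::replace_na(.x, 0))) |>
    dplyr::left_join(mean_age, by = "subject_id") |>
    dplyr::mutate(
      age = dplyr::coalesce(.data$age, fallback_age),
      sex = subjects$sex_code,
      y = as.integer(subjects$is_case)
    )
  structure(out, measure = measure, phecodes = phecodes,
            class = c("aggregate_matrix", class(out)))
}

#' @export
print.aggregate_matrix <- function(x, ...) {
  cat(sprintf("<aggregate_matrix> %d subjects x %d phecodes (measure: %s)\n",
              nrow(x), length(attr(x, "phecodes")), attr(x, "measure")))
  NextMethod()
}
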