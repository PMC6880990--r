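subjects_one_case <- function(diag_age = 70) {
  tibble::tibble(subject_id = "c1", sex = "male", is_case = TRUE,
                 diagnosis_age = diag_age)
}

test_that("left-censoring keeps the window before diagnosis, closed at the near side", {
  visits <- tibble::tibble(subject_id = "c1",
                           age_at_visit = c(63, 67, 69, 71),
                           icd9 = "331.0")
  out <- censor_visits(visits, subjects_one_case(70), "left_censor", 0, 5)
  expect_equal(out$age_at_visit, c(67, 69))
  # diagnosis year itself is included (lo = 0)
  at_diag <- tibble::tibble(subject_id = "c1", age_at_visit = 70, icd9 = "331.0")
  expect_equal(nrow(censor_visits(at_diag, subjects_one_case(70),
                                  "left_censor", 0, 5)), 1L)
})

test_that("age-interval censoring is closed below and accepts an infinite bound", {
  visits <- tibble::tibble(subject_id = "c1", age_at_visit = c(6.9, 7.0, 40),
                           icd9 = "311")
  out <- censor_visits(visits, subjects_one_case(), "age_interval", 7, Inf)
  expect_equal(out$age_at_visit, c(7.0, 40))
})

test_that("right-censoring includes the diagnosis year and excludes the far bound", {
  visits <- tibble::tibble(subject_id = "c1",
                           age_at_visit = c(70, 72, 75, 76),
                           icd9 = "331.0")
  out <- censor_visits(visits, subjects_one_case(70), "right_censor", 0, 5)
  expect_equal(out$age_at_visit, c(70, 72))
})

test_that("censoring never adds rows and is idempotent; bad windows error", {
  set.seed(3)
  subjects <- tibble::tibble(subject_id = letters[1:5], sex = "male",
                             is_case = TRUE, diagnosis_age = runif(5, 40, 80))
  visits <- tibble::tibble(subject_id = sample(letters[1:5], 50, TRUE),
                           age_at_visit = runif(50, 0, 100), icd9 = "311")
  for (mode in c("age_interval", "left_censor", "right_censor")) {
    once <- censor_visits(visits, subjects, mode, 0, 10)
    twice <- censor_visits(once, subjects, mode, 0, 10)
    expect_lte(nrow(once), nrow(visits))
    expect_equal(once, twice)
  }
  expect_error(censor_visits(visits, subjects, "age_interval", 5, 5), "lo < hi")
  no_diag <- dplyr::mutate(subjects, diagnosis_age = NA_real_)
  expect_error(censor_visits(visits, no_diag, "left_censor", 0, 5),
               "missing for")
})

pool_10 <- function() {
  tibble::tibble(
    subject_id = sprintf("p%02d", 1:10),
    sex = rep(c("male", "female"), each = 5),
    age = c(38, 41, 45, 55, 62, 52, 58, 61, 63, 70)
  )
}

test_that("matched controls have exactly the cases' sex distribution", {
  cases <- tibble::tibble(subject_id = c("c1", "c2"),
                          sex = c("male", "female"), age = c(40, 60))
  out <- match_controls(cases, pool_10(), ratio = 1, seed = 11)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$sex), sort(cases$sex))
  # nearest-age neighbour within sex stratum
  expect_equal(out$subject_id[out$case_id == "c1"], "p02")  # age 41
  expect_equal(out$subject_id[out$case_id == "c2"], "p08")  # age 61
})

test_that("an exhausted stratum yields fewer controls with a warning", {
  cases <- tibble::tibble(subject_id = "c1", sex = "female", age = 60)
  small_pool <- dplyr::filter(pool_10(), sex == "female")[1:2, ]
  expect_warning(out <- match_controls(cases, small_pool, ratio = 3, seed = 1),
                 "exhausted")
  expect_equal(nrow(out), 2L)
})

test_that("matching is deterministic given the seed", {
  set.seed(99)
  cases <- tibble::tibble(subject_id = sprintf("c%02d", 1:8),
                          sex = sample(c("male", "female"), 8, TRUE),
                          age = runif(8, 30, 70))
  pool <- tibble::tibble(subject_id = sprintf("p%03d", 1:60),
                         sex = sample(c("male", "female"), 60, TRUE),
                         age = runif(60, 20, 80))
  a <- match_controls(cases, pool, ratio = 2, seed = 7)
  b <- match_controls(cases, pool, ratio = 2, seed = 7)
  expect_identical(a, b)
})

test_that("exclusion-phecode carriers are removed from the pool first", {
  cases <- tibble::tibble(subject_id = "c1", sex = "male", age = 40)
  mapped <- tibble::tibble(subject_id = "p02", age_at_visit = 40,
                           phecode = "296.2")
  out <- match_controls(cases, pool_10(), ratio = 1, exclusions = "296.2",
                        mapped_visits = mapped, seed = 1)
  # p02 (age 41, otherwise nearest) is a carrier; p01 (38) is chosen instead
  expect_equal(out$subject_id, "p01")
  expect_error(match_controls(cases, pool_10(), exclusions = "296.2"),
               "mapped_visits")
})

test_that("controls overlapping cases and matched age quality are enforced", {
  cases <- tibble::tibble(subject_id = "p01", sex = "male", age = 40)
  expect_error(match_controls(cases, pool_10(), seed = 1), "overlaps")

  # mean |age difference| under matching beats a random draw of equal size
  set.seed(123)
  cases <- tibble::tibble(subject_id = sprintf("c%02d", 1:20), sex = "male",
                          age = runif(20, 30, 70))
  pool <- tibble::tibble(subject_id = sprintf("p%03d", 1:200), sex = "male",
                         age = runif(200, 20, 80))
  matched <- match_controls(cases, pool, ratio = 1, seed = 5)
  matched_diff <- mean(abs(matched$age - cases$age[match(matched$case_id,
                                                         cases$subject_id)]))
  random_diffs <- replicate(200, {
    draw <- pool[sample.int(nrow(pool), nrow(cases)), ]
    mean(abs(draw$age - cases$age))
  })
  expect_lte(matched_diff, mean(random_diffs))
})

test_that("matched controls inherit their case's diagnosis age", {
  cases <- tibble::tibble(subject_id = "c1", sex = "male", age = 40,
                          diagnosis_age = 39)
  out <- match_controls(cases, pool_10(), ratio = 1, seed = 1)
  expect_equal(out$diagnosis_age, 39)
})

test_that("aggregate measures follow their definitions on a hand case", {
  mapped <- tibble::tibble(subject_id = c("a", "a"),
                           age_at_visit = c(40.0, 42.5),
                           phecode = "296.2")
  subjects <- tibble::tibble(subject_id = c("a", "b"), sex = "female",
                             is_case = c(TRUE, FALSE), age = c(41, 50))
  for (spec in list(c("binary", 1), c("count", 2), c("duration", 2.5))) {
    m <- aggregate_phecodes(mapped, subjects, measure = spec[[1]])
    expect_equal(m[["296.2"]], c(as.numeric(spec[[2]]), 0))
  }
  m <- aggregate_phecodes(mapped, subjects, measure = "binary")
  expect_equal(m$age, c(41.25, 50))  # mean visit age, fallback reference age
  expect_equal(m$sex, c(1, 1))
  expect_equal(m$y, c(1L, 0L))
})

test_that("the full matrix matches a brute-force tally of listed visits", {
  mapped <- tibble::tibble(
    subject_id = c("a", "a", "a", "b", "b", "c"),
    age_at_visit = c(10, 12, 20, 30, 30, 5),
    phecode = c("296.2", "296.2", "345", "345", "345", "296.2")
  )
  subjects <- tibble::tibble(subject_id = c("a", "b", "c"),
                             sex = c("male", "female", "male"),
                             is_case = c(TRUE, TRUE, FALSE))
  cnt <- aggregate_phecodes(mapped, subjects, measure = "count")
  expect_equal(cnt[["296.2"]], c(2, 0, 1))
  expect_equal(cnt[["345"]], c(1, 2, 0))
  dur <- aggregate_phecodes(mapped, subjects, measure = "duration")
  expect_equal(dur[["296.2"]], c(2, 0, 0))
  expect_equal(dur[["345"]], c(0, 0, 0))
})

test_that("binary/count/duration obey their joint invariants on random data", {
  set.seed(8)
  mapped <- tibble::tibble(
    subject_id = sample(letters[1:15], 120, TRUE),
    age_at_visit = runif(120, 0, 90),
    phecode = sample(c("296.2", "345", "365"), 120, TRUE)
  )
  subjects <- tibble::tibble(subject_id = letters[1:20],
                             sex = sample(c("male", "female"), 20, TRUE),
                             is_case = rep(c(TRUE, FALSE), 10))
  b <- aggregate_phecodes(mapped, subjects, "binary")
  k <- aggregate_phecodes(mapped, subjects, "count")
  d <- aggregate_phecodes(mapped, subjects, "duration")
  for (p in c("296.2", "345", "365")) {
    expect_equal(b[[p]] == 1, k[[p]] >= 1)
    expect_true(all(k[[p]][d[[p]] > 0] >= 2))
    expect_true(all(b[[p]] %in% c(0, 1)))
    expect_true(all(k[[p]] == round(k[[p]]) & k[[p]] >= 0))
    expect_true(all(d[[p]] >= 0))
  }
})

test_that("subjects of unknown sex are excluded with a warning", {
  mapped <- tibble::tibble(subject_id = "a", age_at_visit = 10,
                           phecode = "296.2")
  subjects <- tibble::tibble(subject_id = c("a", "b"),
                             sex = c("female", "unknown"),
                             is_case = c(TRUE, FALSE))
  expect_warning(m <- aggregate_phecodes(mapped, subjects, "binary"),
                 "unknown sex")
  expect_equal(nrow(m), 1L)
})
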