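asd_null <- null_interval(c(0.3, 1.5))

test_that("null_interval transforms OR bounds to the log scale and validates", {
  expect_equal(asd_null$lo, log(0.3))
  expect_equal(asd_null$hi, log(1.5))
  expect_error(null_interval(c(1.5, 0.3)), "lo < hi")
  expect_error(null_interval(c(-1, 1.5)), "lo < hi")
  expect_warning(null_interval(c(1.2, 1.5)), "does not contain OR = 1")
  # asymmetric zones as used for severe outcomes are legal
  expect_silent(null_interval(c(0.3, 1.1)))
})

test_that("second-generation p-value is 0 iff intervals are disjoint", {
  expect_equal(sgpv(1.62, 9.90, asd_null, scale = "or"), 0)
  # touching intervals are not disjoint: overlap has zero length -> still 0
  expect_equal(sgpv(asd_null$hi, asd_null$hi + 1, asd_null), 0)
  expect_gt(sgpv(asd_null$hi - 0.01, asd_null$hi + 1, asd_null), 0)
  # interval entirely below the null (protective direction) is also 0
  expect_equal(sgpv(0.05, 0.2, asd_null, scale = "or"), 0)
})

test_that("second-generation p-value is 1 iff contained with |I| <= 2|N|", {
  expect_equal(sgpv(asd_null$lo, asd_null$hi, asd_null), 1)
  expect_equal(sgpv(log(0.9), log(1.1), asd_null), 1)
  # containment fails -> below 1
  expect_lt(sgpv(asd_null$lo - 0.1, asd_null$hi, asd_null), 1)
})

test_that("partial overlap matches the hand computation on the log scale", {
  expect_equal(sgpv(1.0, 2.0, asd_null, scale = "or"), log(1.5) / log(2.0))
})

test_that("the small-sample correction caps wide-interval p-values at one half", {
  wide <- 4 * (asd_null$hi - asd_null$lo)
  p <- sgpv(asd_null$lo - wide / 2, asd_null$hi + wide / 2, asd_null)
  # |I| > 2|N| so p = |I cap N| / (2|N|) = 1/2
  expect_equal(p, 0.5)
})

test_that("p = 0 calls are identical on the OR and log scales", {
  set.seed(61)
  for (i in 1:50) {
    lo <- runif(1, -3, 2)
    hi <- lo + runif(1, 0.01, 3)
    p_log <- sgpv(lo, hi, asd_null)
    p_or <- sgpv(exp(lo), exp(hi), asd_null, scale = "or")
    expect_equal(p_log, p_or, tolerance = 1e-12)
    expect_gte(p_log, 0)
    expect_lte(p_log, 1)
  }
})

test_that("degenerate interval estimates are rejected", {
  expect_error(sgpv(1, 1, asd_null), "degenerate")
  expect_error(sgpv(0, 2, asd_null, scale = "or"), "positive")
  expect_error(sgpv(-Inf, 1, asd_null), "finite")
})

test_that("classification maps 0 / (0,1) / 1 to the three calls", {
  cls <- sgpv_class(c(0, 0.4, 1, NA))
  expect_equal(as.character(cls), c("significant", "inconclusive",
                                    "confirmed_null", NA))
})

test_that("the power function hits its limit cases", {
  se <- 0.2
  expect_gt(sgpv_power(asd_null$hi + 10 * se, se, asd_null), 0.999)
  mid <- (asd_null$lo + asd_null$hi) / 2
  narrow_se <- (asd_null$hi - asd_null$lo) / 10
  expect_lt(sgpv_power(mid, narrow_se, asd_null), 1e-6)
})

test_that("the power function is symmetric about a symmetric null's midpoint", {
  sym <- null_interval(c(1 / 1.5, 1.5))
  for (d in c(0.1, 0.5, 1.2)) {
    expect_equal(sgpv_power(d, 0.3, sym), sgpv_power(-d, 0.3, sym),
                 tolerance = 1e-12)
  }
})

test_that("analytic power matches the Monte-Carlo decision-rule oracle", {
  set.seed(71)
  grid <- expand.grid(theta = c(-1.5, 0.2, 0.6, 1.1, 1.8),
                      se = c(0.1, 0.3))
  for (i in seq_len(nrow(grid))) {
    p_hat <- mc_power(grid$theta[i], grid$se[i], asd_null, n_draws = 1e5)
    p_an <- sgpv_power(grid$theta[i], grid$se[i], asd_null)
    mc_se <- sqrt(max(p_an * (1 - p_an), 1e-12) / 1e5)
    expect_lt(abs(p_hat - p_an), 3 * mc_se + 1e-6)
  }
})

test_that("prior limits collapse the PPV to its endpoints", {
  expect_equal(ppv_sgpv(log(2), log(6), asd_null, pi0 = 1), 0)
  expect_equal(as.numeric(ppv_sgpv(log(2), log(6), asd_null, pi0 = 0)), 1)
})

test_that("a CI equal to the null interval gives PPV one half at pi0 = 0.5", {
  # f1 then equals f0, so the averaged powers cancel in the Bayes factor
  expect_equal(ppv_sgpv(asd_null$lo, asd_null$hi, asd_null, pi0 = 0.5), 0.5,
               tolerance = 1e-10)
})

test_that("quadrature PPV agrees with the Monte-Carlo oracle", {
  set.seed(83)
  configs <- list(
    list(ci = log(c(1.62, 9.90)), null = asd_null),
    list(ci = log(c(2.0, 3.5)), null = asd_null),
    list(ci = log(c(1.4, 2.2)), null = asd_null),
    list(ci = log(c(0.9, 4.0)), null = null_interval(c(0.3, 1.1))),
    list(ci = c(-0.5, 1.2), null = asd_null)
  )
  for (cf in configs) {
    q <- as.numeric(ppv_sgpv(cf$ci[1], cf$ci[2], cf$null))
    m <- mc_ppv(cf$ci[1], cf$ci[2], cf$null, n_draws = 2e5)
    expect_lt(abs(q - m), 0.015)
    expect_gte(q, 0)
    expect_lte(q, 1)
  }
})

test_that("PPV decreases as the prior null probability grows", {
  ci <- log(c(1.8, 6))
  pi0s <- seq(0.1, 0.9, by = 0.2)
  vals <- vapply(pi0s, function(p) as.numeric(ppv_sgpv(ci[1], ci[2], asd_null,
                                                       pi0 = p)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("add_sgpv annotates screen output and skips unusable fits", {
  set.seed(91)
  mat <- carriage_matrix(800, 0.1, log(6), phecode = "201.1")
  mat$`202.1` <- c(rep(1, 3), rep(0, nrow(mat) - 3))  # below carrier filter
  res <- run_screen(mat, phecodes = c("201.1", "202.1")) |>
    add_sgpv(asd_null)
  strong <- res[res$phecode == "201.1", ]
  expect_equal(strong$p_delta, 0)
  expect_equal(as.character(strong$classification), "significant")
  expect_gt(strong$ppv, 0.5)
  expect_false(strong$negative_direction)
  skipped <- res[res$phecode == "202.1", ]
  expect_true(is.na(skipped$p_delta))
  expect_true(is.na(skipped$ppv))
})

test_that("protective findings carry the negative-direction flag, same p-value", {
  res <- tibble::tibble(
    phecode = "x", theta = log(0.1), se = 0.2,
    ci_lo = log(0.08), ci_hi = log(0.15),
    or = 0.1, or_lo = 0.08, or_hi = 0.15,
    converged = TRUE, separation = FALSE,
    case_carriers = 50L, control_carriers = 200L, n_used = 1000L,
    skip_reason = NA_character_
  ) |> add_sgpv(asd_null)
  expect_equal(res$p_delta, 0)
  expect_true(res$negative_direction)
})

test_that("p = 0 call rates on null effects fall as samples grow", {
  # the screening analogue of type-I error going to zero with n
  rates <- vapply(c(500, 2000, 8000), function(n) {
    sgpv_power(0, se = 2 / sqrt(n * 0.1), asd_null)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})
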