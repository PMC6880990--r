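#' Define an interval null ("indifference zone") for odds ratios
#'
#' The screen declares a finding clinically interesting only when the whole
#' confidence interval lies outside a pre-specified interval of effect sizes
#' judged uninteresting a priori — e.g. odds ratios in `[0.3, 1.5]`. The
#' interval is stated on the odds-ratio scale, as clinicians think in odds
#' ratios, and carried internally on the log-odds scale where the regression
#' coefficient lives (interval overlap proportions depend on the scale, so
#' one canonical scale must be fixed).
#'
#' @param or Length-2 numeric, the null interval on the odds-ratio scale,
#'   `0 < lo < hi`. A zone not containing OR = 1 is accepted with a warning —
#'   an indifference zone that excludes "no effect" is almost always a
#'   misconfiguration.
#' @return A `null_interval`: list with `lo`, `hi` on the log-odds scale and
#'   `or` as given.
#' @examples
#' null_interval(c(0.3, 1.5))
#' @export
null_interval <- function(or) {
  stopifnot(is.numeric(or), length(or) == 2)
  if (!(or[1] > 0 && or[1] < or[2])) {
    stop("null interval requires 0 < lo < hi on the odds-ratio scale",
         call. = FALSE)
  }
  if (or[1] > 1 || or[2] < 1) {
    warning("null interval does not contain OR = 1 (no effect)", call. = FALSE)
  }
  structure(list(lo = log(or[1]), hi = log(or[2]), or = as.numeric(or)),
            class = "null_interval")
}

#' @export
print.null_interval <- function(x, ...) {
  cat(sprintf("<null_interval> OR [%g, %g]  (log-odds [%.4f, %.4f])\n",
              x$or[1], x$or[2], x$lo, x$hi))
  invisible(x)
}

as_null_interval <- function(x) {
  if (inherits(x, "null_interval")) return(x)
  null_interval(x)
}

#' Second-generation p-value of an interval estimate against an interval null
#'
#' The second-generation p-value is the fraction of the data-supported effect
#' sizes (the interval estimate `I`) lying inside the interval null `N`, with
#' a small-sample correction for intervals much wider than the null:
#'
#' `p = |I∩N| / |I|` when `|I| <= 2|N|`, and `p = |I∩N| / (2|N|)` for
#' intervals more than twice as wide as the null (an interval that wide is
#' evidence of a small sample, not of overlap, so its denominator is capped).
#' `p = 0` iff the intervals are disjoint (the data support only
#' clinically relevant effect sizes); `p = 1` iff `I` lies inside `N` and
#' `|I| <= 2|N|` (the data support only null effects). All lengths are taken
#' on the log-odds scale, so the 0/1 calls are identical whether the inputs
#' are stated on the OR or the log scale.
#'
#' @param lo,hi Interval estimate bounds (vectorized). On the log-odds scale
#'   by default; set `scale = "or"` for odds-ratio-scale input.
#' @param null A [null_interval()] (or a length-2 OR-scale numeric).
#' @param scale `"log"` (default) or `"or"` for the estimate bounds.
#' @return Numeric vector of second-generation p-values in `[0, 1]`.
#' @examples
#' asd_null <- null_interval(c(0.3, 1.5))
#' sgpv(1.62, 9.90, asd_null, scale = "or")  # disjoint from the null: 0
#' sgpv(1.0, 2.0, asd_null, scale = "or")    # partial overlap: log(1.5)/log(2)
#' @export
sgpv <- function(lo, hi, null, scale = c("log", "or")) {
  scale <- match.arg(scale)
  null <- as_null_interval(null)
  if (scale == "or") {
    if (any(lo <= 0 | hi <= 0)) {
      stop("odds-ratio-scale bounds must be positive", call. = FALSE)
    }
    lo <- log(lo)
    hi <- log(hi)
  }
  if (any(!is.finite(lo) | !is.finite(hi))) {
    stop("interval estimate bounds must be finite", call. = FALSE)
  }
  if (any(hi <= lo)) {
    stop("degenerate interval estimate: requires lo < hi", call. = FALSE)
  }
  len_i <- hi - lo
  len_n <- null$hi - null$lo
  overlap <- pmax(0, pmin(hi, null$hi) - pmax(lo, null$lo))
  ifelse(len_i <= 2 * len_n, overlap / len_i, overlap / (2 * len_n))
}

#' Classify second-generation p-values
#'
#' `p = 0` is a significant (clinically relevant) finding, `p = 1` confirms
#' the null, anything in between is inconclusive.
#'
#' @param p_delta Numeric vector of second-generation p-values.
#' @return Factor with levels `significant`, `inconclusive`, `confirmed_null`.
#' @export
sgpv_class <- function(p_delta) {
  factor(
    dplyr::case_when(
      is.na(p_delta) ~ NA_character_,
      p_delta == 0 ~ "significant",
      p_delta == 1 ~ "confirmed_null",
      .default = "inconclusive"
    ),
    levels = c("significant", "inconclusive", "confirmed_null")
  )
}

#' Probability of a second-generation p-value of zero, given the true effect
#'
#' Under the asymptotic normal model `theta_hat ~ N(theta, se^2)`, the Wald
#' interval at `level` misses the null interval entirely — i.e. `p = 0` —
#' exactly when `theta_hat + z*se < lo` or `theta_hat - z*se > hi`, giving
#' the two-tailed power function
#'
#' \deqn{P(p_\delta = 0 \mid \theta) =
#'   \Phi\!\left(\frac{\theta_0^- - \theta}{se} - z\right) +
#'   \Phi\!\left(\frac{\theta - \theta_0^+}{se} - z\right)}
#'
#' with `z` the two-sided `level` quantile. Vectorized over `theta`.
#'
#' @param theta True effect(s) on the log-odds scale.
#' @param se Standard error of the estimator, `> 0`.
#' @param null A [null_interval()].
#' @param level Confidence level of the interval estimate, default 0.95.
#' @return Probabilities in `(0, 1)`.
#' @export
sgpv_power <- function(theta, se, null, level = 0.95) {
  stopifnot(se > 0, level > 0, level < 1)
  null <- as_null_interval(null)
  z <- stats::qnorm(1 - (1 - level) / 2)
  stats::pnorm((null$lo - theta) / se - z) +
    stats::pnorm((theta - null$hi) / se - z)
}

#' Empirical-Bayes positive predictive value of a significant finding
#'
#' Estimates `P(alternative true | p_delta = 0)` for a finding. With prior
#' null probability `pi0`, the Bayes factor form is
#'
#' \deqn{PPV = 1 - \left[1 + \frac{1-\tilde\beta}{\tilde\alpha}\cdot
#'       \frac{1-\pi_0}{\pi_0}\right]^{-1}}
#'
#' where `alpha~` averages the `p = 0` power over the null interval
#' (`theta ~ Uniform[null lo, null hi]`) and `1 - beta~` averages it over the
#' observed uncertainty interval (`theta ~ Uniform[ci_lo, ci_hi]`) — the
#' empirical-Bayes twist: the alternative weight function is taken from the
#' data. Both integrals are evaluated by fixed 64-node Gauss–Legendre
#' quadrature, so the result is deterministic.
#'
#' The standard error entering the power function is recovered from the Wald
#' interval width, `se = (ci_hi - ci_lo) / (2 z)`, unless given explicitly.
#'
#' @param ci_lo,ci_hi Observed confidence bounds on the log-odds scale.
#' @param null A [null_interval()].
#' @param pi0 Prior probability of the null, in `[0, 1]`; default 0.5
#'   (non-informative).
#' @param level Confidence level of the interval, default 0.95.
#' @param se Standard error on the log-odds scale; derived from the interval
#'   width when `NULL`.
#' @return PPV in `[0, 1]`. If the null-average power underflows to zero the
#'   PPV is clamped to 1 and carries attribute `alpha_underflow = TRUE`.
#' @examples
#' nl <- null_interval(c(0.3, 1.5))
#' ppv_sgpv(log(1.62), log(9.90), nl)
#' @export
ppv_sgpv <- function(ci_lo, ci_hi, null, pi0 = 0.5, level = 0.95, se = NULL) {
  stopifnot(length(ci_lo) == 1, length(ci_hi) == 1, ci_hi > ci_lo,
            pi0 >= 0, pi0 <= 1)
  null <- as_null_interval(null)
  if (pi0 == 0) return(1)
  if (pi0 == 1) return(0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (is.null(se)) se <- (ci_hi - ci_lo) / (2 * z)
  stopifnot(se > 0)

  alpha <- gl_mean(function(t) sgpv_power(t, se, null, level), null$lo, null$hi)
  power1 <- gl_mean(function(t) sgpv_power(t, se, null, level), ci_lo, ci_hi)

  if (alpha <= 0 || !is.finite(power1 / alpha)) {
    return(structure(1, alpha_underflow = TRUE))
  }
  1 - 1 / (1 + (power1 / alpha) * ((1 - pi0) / pi0))
}

# mean of f over [a, b] by 64-node Gauss-Legendre quadrature
gl_mean <- function(f, a, b, n = 64L) {
  q <- pracma::gaussLegendre(n, a, b)
  sum(q$w * f(q$x)) / (b - a)
}

#' Attach second-generation p-values and PPVs to screen results
#'
#' For each converged, non-separated fit the second-generation p-value of its
#' Wald interval against `null` is computed; findings with `p = 0` get an
#' empirical-Bayes PPV. A `negative_direction` flag marks significant findings
#' whose interval lies entirely below the null interval (decreased odds —
#' typically of less clinical interest); the flag never alters the p-value.
#'
#' @param screen Output of [run_screen()].
#' @param null A [null_interval()] (or length-2 OR-scale numeric).
#' @param pi0 Prior null probability for the PPV, default 0.5.
#' @return The screen tibble with columns `p_delta`, `classification`, `ppv`,
#'   `negative_direction` added. Skipped or separated phecodes carry `NA`.
#' @export
add_sgpv <- function(screen, null, pi0 = 0.5) {
  null <- as_null_interval(null)
  screen <- tibble::as_tibble(screen)
  usable <- screen$converged & !screen$separation & !is.na(screen$ci_lo)
  p <- rep(NA_real_, nrow(screen))
  if (any(usable)) {
    p[usable] <- sgpv(screen$ci_lo[usable], screen$ci_hi[usable], null)
  }
  ppv <- rep(NA_real_, nrow(screen))
  sig <- which(!is.na(p) & p == 0)
  level <- attr(screen, "level") %||% 0.95
  for (i in sig) {
    ppv[i] <- as.numeric(ppv_sgpv(screen$ci_lo[i], screen$ci_hi[i], null,
                                  pi0 = pi0, level = level, se = screen$se[i]))
  }
  screen$p_delta <- p
  screen$classification <- sgpv_class(p)
  screen$ppv <- ppv
  screen$negative_direction <- !is.na(p) & p == 0 & screen$ci_hi < null$lo
  attr(screen, "null_interval") <- null
  attr(screen, "pi0") <- pi0
  screen
}
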