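#' Fit the per-phecode logistic mean model
#'
#' Fits, by maximum likelihood, `logit P(case) = b0 + bm * m + ba * age +
#' bs * sex` where `m` is the phecode's aggregate measure, and returns the
#' coefficient of interest `bm` — the log odds ratio for the phecode —
#' together with its Wald confidence interval. Covariates are dropped when
#' `covariates = FALSE` or when a covariate column is absent or constant.
#'
#' Complete or quasi-complete separation (e.g. a phecode carried by cases
#' only) is flagged via `separation`/`converged`, never raised: such phecodes
#' are excluded from the downstream second-generation p-value and PPV steps
#' and reported separately.
#'
#' @param matrix An [aggregate_phecodes()] matrix (or any data frame with the
#'   phecode column plus `age`, `sex`, `y`).
#' @param phecode Name of the phecode column to test.
#' @param level Confidence level for the Wald interval, default 0.95.
#' @param covariates Include age and sex? Default `TRUE`.
#' @return A `phe_fit` object; see [tidy.phe_fit()] and [glance.phe_fit()].
#' @examples
#' m <- tibble::tibble(
#'   "008" = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)),
#'   age = 50, sex = 1, y = rep(c(1L, 0L), c(100, 100))
#' )
#' fit <- fit_phecode(m, "008", covariates = FALSE)
#' exp(fit$theta_hat)  # odds ratio, equals the 2x2 cross-product ratio
#' @export
fit_phecode <- function(matrix, phecode, level = 0.95, covariates = TRUE) {
  if (!phecode %in% names(matrix)) {
    stop("phecode column not found in matrix: ", phecode, call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  df <- tibble::tibble(
    m = as.numeric(matrix[[phecode]]),
    y = as.integer(matrix$y)
  )
  use_age <- covariates && "age" %in% names(matrix) &&
    dplyr::n_distinct(matrix$age, na.rm = TRUE) > 1L
  use_sex <- covariates && "sex" %in% names(matrix) &&
    dplyr::n_distinct(matrix$sex, na.rm = TRUE) > 1L
  if (use_age) df$age <- as.numeric(matrix$age)
  if (use_sex) df$sex <- as.numeric(matrix$sex)
  df <- df[stats::complete.cases(df), ]

  case_carriers <- sum(df$m > 0 & df$y == 1L)
  control_carriers <- sum(df$m > 0 & df$y == 0L)

  form <- stats::as.formula(paste("y ~ m",
                                  if (use_age) "+ age" else "",
                                  if (use_sex) "+ sex" else ""))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  theta <- unname(sm["m", "Estimate"])
  se <- unname(sm["m", "Std. Error"])
  # quasi-separation inflates |theta| and se without tripping glm's warning
  separation <- sep_warn || !fit$converged || abs(theta) > 15 || se > 100 ||
    case_carriers == 0L || control_carriers == 0L
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(
      phecode = phecode,
      theta_hat = theta, se = se,
      lo = theta - z * se, hi = theta + z * se,
      level = level,
      converged = fit$converged && !separation,
      separation = separation,
      case_carriers = case_carriers,
      control_carriers = control_carriers,
      n_used = nrow(df),
      covariates = c(age = use_age, sex = use_sex),
      deviance = fit$deviance,
      null_deviance = fit$null.deviance,
      aic = fit$aic
    ),
    class = "phe_fit"
  )
}

#' @export
print.phe_fit <- function(x, ...) {
  cat(sprintf(
    "<phe_fit> phecode %s: OR %.3f [%.3f, %.3f] (level %.2f)%s\n",
    x$phecode, exp(x$theta_hat), exp(x$lo), exp(x$hi), x$level,
    if (x$separation) " [separation]" else ""
  ))
  invisible(x)
}

#' Tidy a per-phecode fit
#'
#' @param x A `phe_fit`.
#' @param ... Unused.
#' @return One-row tibble: `phecode`, `theta`, `se`, `ci_lo`, `ci_hi` (log-odds
#'   scale), `or`, `or_lo`, `or_hi`, `converged`, `separation`,
#'   `case_carriers`, `control_carriers`, `n_used`.
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.phe_fit <- function(x, ...) {
  tibble::tibble(
    phecode = x$phecode,
    theta = x$theta_hat, se = x$se, ci_lo = x$lo, ci_hi = x$hi,
    or = exp(x$theta_hat), or_lo = exp(x$lo), or_hi = exp(x$hi),
    converged = x$converged, separation = x$separation,
    case_carriers = x$case_carriers, control_carriers = x$control_carriers,
    n_used = x$n_used
  )
}

#' One-row model summary for a per-phecode fit
#'
#' @param x A `phe_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_used`, `deviance`, `null_deviance`, `aic`,
#'   `level`, `converged`.
#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.phe_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used, deviance = x$deviance,
    null_deviance = x$null_deviance, aic = x$aic,
    level = x$level, converged = x$converged
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' Run the logistic screen across phecodes
#'
#' Fits [fit_phecode()] for every phecode with at least `min_carriers`
#' carriers in each class; phecodes below the threshold are reported in the
#' output with `skip_reason` set (count conservation: fitted rows + skipped
#' rows = phecodes requested). Output rows are sorted by phecode, so repeated
#' runs are identical.
#'
#' @param matrix An [aggregate_phecodes()] matrix.
#' @param phecodes Phecode columns to screen; defaults to the matrix's
#'   `phecodes` attribute (all of them).
#' @param level Confidence level, default 0.95.
#' @param min_carriers Minimum carriers required in each of the case and
#'   control classes, default 5.
#' @param covariates Include age and sex covariates, default `TRUE`.
#' @return Tibble, one row per phecode, columns as [tidy.phe_fit()] plus
#'   `skip_reason` (`NA` for fitted phecodes).
#' @export
run_screen <- function(matrix, phecodes = NULL, level = 0.95,
                       min_carriers = 5L, covariates = TRUE) {
  stopifnot(min_carriers >= 0L)
  if (is.null(phecodes)) phecodes <- attr(matrix, "phecodes")
  if (is.null(phecodes)) {
    phecodes <- setdiff(names(matrix), c("subject_id", "age", "sex", "y"))
  }
  phecodes <- sort(unique(phecodes))
  if (length(phecodes) == 0) return(empty_screen_tbl())

  rows <- purrr::map(phecodes, function(p) {
    cc <- sum(matrix[[p]] > 0 & matrix$y == 1L)
    kc <- sum(matrix[[p]] > 0 & matrix$y == 0L)
    if (cc < min_carriers || kc < min_carriers) {
      return(tibble::tibble(
        phecode = p, theta = NA_real_, se = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_,
        or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
        converged = FALSE, separation = FALSE,
        case_carriers = cc, control_carriers = kc,
        n_used = 0L,
        skip_reason = sprintf("fewer than %d carriers in a class", min_carriers)
      ))
    }
    out <- tidy(fit_phecode(matrix, p, level = level, covariates = covariates))
    out$skip_reason <- NA_character_
    out
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "level") <- level
  out
}

empty_screen_tbl <- function() {
  tibble::tibble(
    phecode = character(), theta = numeric(), se = numeric(),
    ci_lo = numeric(), ci_hi = numeric(),
    or = numeric(), or_lo = numeric(), or_hi = numeric(),
    converged = logical(), separation = logical(),
    case_carriers = integer(), control_carriers = integer(),
    n_used = integer(), skip_reason = character()
  )
}
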