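#' Default age schedules for the synthetic mortality surface
#'
#' `default_age_baseline()` returns baseline log annual death rates `a_x` for
#' age months 0-59: a steep decline from a high neonatal hazard to a low,
#' nearly flat child hazard, chosen so that the implied rates at the anchor
#' of the time index (`k = 0`) are roughly NMR 48, IMR 130, and U5MR 165
#' per 1,000 live births -- levels typical of sub-Saharan Africa in the
#' early 1990s.
#' `default_age_loadings()` returns age loadings `b_x` (nonnegative, summing
#' to 1) that increase with age, so postneonatal and child mortality fall
#' faster than neonatal mortality as the time index declines -- the age
#' imbalance that motivates monthly-resolution analysis.
#'
#' @return Numeric vector of length 60.
#' @examples
#' exp(default_age_baseline())[1:3]  # annual death rates at ages 0-2 months
#' sum(default_age_loadings())       # 1
#' @export
default_age_baseline <- function() {
  x <- 0:59
  # annual hazard: exponential decline from the neonatal month plus a floor
  log(0.58 * exp(-0.45 * x) + 0.010)
}

#' @rdname default_age_baseline
#' @export
default_age_loadings <- function() {
  x <- 0:59
  b <- 0.5 + x / 59
  b / sum(b)
}

#' Generate a ground-truth mortality surface
#'
#' Builds an age-by-year surface of true annual death rates
#' `m[x, t] = exp(a_x + b_x * k_t + e_xt)` for age months 0-59, where the
#' period index `k_t` follows a random walk with drift, anchored so that
#' `sum(k_t) = 0`, and `e_xt` is independent Gaussian age-period noise.
#' This is the generative twin of the Lee-Carter decomposition fitted by
#' [fit_lc()], so downstream recovery of `a_x`, `b_x`, `k_t` can be tested
#' against known truth.
#'
#' @param years Inclusive calendar-year range covered by the surface.
#' @param a_x Baseline log annual death rate per age month (length 60).
#' @param b_x Age loadings; must be nonnegative and sum to 1 (length 60).
#' @param k_drift Per-year drift of the period index `k_t` (negative values
#'   give declining mortality).
#' @param k_sigma Innovation standard deviation of the `k_t` random walk.
#' @param e_sigma Standard deviation of the age-period noise on the log scale.
#' @param seed Optional integer seed; if supplied the surface is reproducible.
#'
#' @return A tibble of class `u5_surface` with columns `age_month`, `year`,
#'   `m` (true annual death rate), carrying the generating `a_x`, `b_x`,
#'   `k_t` in `attr(, "truth")`.
#' @examples
#' surf <- make_true_surface(years = 2000:2004, k_sigma = 0, e_sigma = 0,
#'                           seed = 1)
#' surface_matrix(surf)[1:3, ]
#' @export
make_true_surface <- function(years = 1990:2017,
                              a_x = default_age_baseline(),
                              b_x = default_age_loadings(),
                              k_drift = -1.8,
                              k_sigma = 0.15,
                              e_sigma = 0.05,
                              seed = NULL) {
  check_finite(years, "years")
  check_finite(a_x, "a_x")
  check_finite(b_x, "b_x")
  check_finite(k_drift, "k_drift")
  check_finite(k_sigma, "k_sigma")
  check_finite(e_sigma, "e_sigma")
  if (length(a_x) != 60L || length(b_x) != 60L) {
    abort("a_x and b_x must cover exactly 60 age months (0-59)")
  }
  if (any(b_x < 0)) abort("field `b_x` must be nonnegative")
  if (abs(sum(b_x) - 1) > 1e-8) abort("field `b_x` must sum to 1")
  if (k_sigma < 0) abort("field `k_sigma` must be nonnegative")
  if (e_sigma < 0) abort("field `e_sigma` must be nonnegative")
  years <- seq(min(years), max(years))
  ny <- length(years)

  if (!is.null(seed)) set.seed(as.integer(seed))
  innov <- if (ny > 1) rnorm(ny - 1, mean = k_drift, sd = k_sigma) else numeric(0)
  k <- cumsum(c(0, innov))
  k <- k - mean(k)                       # anchor: sum(k_t) = 0
  e <- matrix(rnorm(60L * ny, sd = e_sigma), nrow = 60L)

  logm <- outer(a_x, rep(1, ny)) + outer(b_x, k) + e
  out <- tibble(
    age_month = rep(0:59, times = ny),
    year = rep(years, each = 60L),
    m = as.vector(exp(logm))
  )
  structure(out,
    class = c("u5_surface", class(out)),
    truth = list(a_x = a_x, b_x = b_x, k_t = setNames(k, years),
                 k_drift = k_drift, k_sigma = k_sigma, e_sigma = e_sigma)
  )
}

#' Convert a long surface to a 60 x years matrix
#'
#' @param surface A long tibble with `age_month`, `year`, and a value column.
#' @param value Name of the value column (default `"m"`).
#' @return A 60-row matrix, rows age months 0-59, columns the sorted years
#'   (as `colnames`).
#' @export
surface_matrix <- function(surface, value = "m") {
  years <- sort(unique(surface$year))
  mat <- matrix(NA_real_, nrow = 60L, ncol = length(years),
                dimnames = list(0:59, years))
  mat[cbind(surface$age_month + 1L, match(surface$year, years))] <-
    surface[[value]]
  mat
}

#' Survey design and reporting-bias settings for the simulator
#'
#' `survey_design()` describes a single retrospective full-birth-history
#' survey: how many women are interviewed, when, how many births each woman
#' has on average, how far back the observation window reaches, and how
#' dispersed sampling weights are around 1. `bias_config()` holds the two
#' optional reporting distortions: survivor bias (mothers whose children died
#' are more likely to be missing from the sample) and age heaping at 12
#' months (deaths at 10-14 months reported as exactly 12 months).
#'
#' @param n_women Number of respondent women.
#' @param interview_cmc Interview date as a century-month code (see [cmc()]).
#' @param fertility_mean Mean number of births per woman over her window
#'   (births are Poisson, birth months uniform over the window).
#' @param window_years Retrospective window length in years before the
#'   interview, between 1 and 25.
#' @param weight_dispersion Standard deviation of sampling weights around 1
#'   (0 gives all weights exactly 1).
#' @param survivor_bias Probability scale in `[0, 1]`: a mother with `d` dead
#'   children is removed from the sample with probability
#'   `1 - (1 - survivor_bias)^d`.
#' @param heaping_at_12m Probability that a death at age 10-14 months is
#'   reported as exactly 12 months.
#' @return A named list of class `u5_design` / `u5_bias`.
#' @export
survey_design <- function(n_women = 8000,
                          interview_cmc = cmc(2018, 1),
                          fertility_mean = 6,
                          window_years = 25,
                          weight_dispersion = 0) {
  check_finite(n_women, "n_women")
  check_finite(interview_cmc, "interview_cmc")
  check_finite(fertility_mean, "fertility_mean")
  check_finite(window_years, "window_years")
  check_finite(weight_dispersion, "weight_dispersion")
  if (n_women <= 0) abort("field `n_women` must be positive")
  if (window_years < 1 || window_years > 25) {
    abort("field `window_years` must be between 1 and 25")
  }
  structure(list(n_women = as.integer(n_women),
                 interview_cmc = as.integer(interview_cmc),
                 fertility_mean = fertility_mean,
                 window_years = window_years,
                 weight_dispersion = weight_dispersion),
            class = "u5_design")
}

#' @rdname survey_design
#' @export
bias_config <- function(survivor_bias = 0, heaping_at_12m = 0) {
  check_finite(survivor_bias, "survivor_bias")
  check_finite(heaping_at_12m, "heaping_at_12m")
  if (survivor_bias < 0 || survivor_bias > 1) {
    abort("field `survivor_bias` must be in [0, 1]")
  }
  if (heaping_at_12m < 0 || heaping_at_12m > 1) {
    abort("field `heaping_at_12m` must be in [0, 1]")
  }
  structure(list(survivor_bias = survivor_bias,
                 heaping_at_12m = heaping_at_12m),
            class = "u5_bias")
}

#' Simulate full-birth-history survey records
#'
#' Draws women, gives each a Poisson number of births with uniform birth
#' months over the retrospective window, and walks each child through
#' monthly survival: in age month `x` reached in calendar year `t`, the
#' child dies with the monthly probability obtained from the surface's
#' annual rate `m[x, t]` via [m_to_q()]. Survival is censored at the
#' interview month; sub-month timing is never simulated. Children whose
#' simulated death month falls at or after the interview are reported alive.
#' Records outside the tabulation window are still emitted (truncation is
#' applied downstream by [tabulate_events()]). Reporting biases are applied
#' last: survivor bias removes whole mothers with probability growing in the
#' number of their dead children, and heaping rewrites deaths at 10-14
#' months as exactly 12 months. Because biases are drawn after the survival
#' pass, two runs under the same seed share the identical pre-bias record
#' stream.
#'
#' @param surface A `u5_surface` (or any long tibble with `age_month`,
#'   `year`, `m`) covering the design's retrospective window.
#' @param design A [survey_design()].
#' @param bias A [bias_config()].
#' @param seed Optional integer seed.
#' @return A tibble (class `u5_birth_records`) with one row per ever-born
#'   child: `woman_id`, `child_id`, `dob_cmc`, `died`, `death_age_months`
#'   (NA when alive), `interview_cmc`, `weight`.
#' @export
simulate_birth_histories <- function(surface,
                                     design = survey_design(),
                                     bias = bias_config(),
                                     seed = NULL) {
  stopifnot(inherits(design, "u5_design"), inherits(bias, "u5_bias"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  mat <- surface_matrix(surface)
  years <- as.integer(colnames(mat))
  window_start_cmc <- design$interview_cmc - 12L * round(design$window_years)
  if (cmc_year(window_start_cmc) < min(years)) {
    abort(sprintf(
      "retrospective window starts in %d but the surface begins in %d",
      cmc_year(window_start_cmc), min(years)))
  }

  n_births <- rpois(design$n_women, design$fertility_mean)
  woman_id <- rep(seq_len(design$n_women), n_births)
  n_child <- length(woman_id)
  dob <- window_start_cmc +
    sample.int(design$interview_cmc - window_start_cmc, n_child, replace = TRUE) - 1L

  # monthly survival pass, vectorized over children age by age
  death_age <- rep(NA_integer_, n_child)
  alive <- rep(TRUE, n_child)
  for (x in 0:59) {
    cm <- dob + x
    at_risk <- alive & cm < design$interview_cmc
    if (!any(at_risk)) next
    yr <- cmc_year(cm[at_risk])
    yi <- match(yr, years)
    q <- m_to_q(mat[cbind(x + 1L, yi)])
    dies <- runif(sum(at_risk)) < q
    idx <- which(at_risk)[dies]
    death_age[idx] <- x
    alive[idx] <- FALSE
  }

  died <- !is.na(death_age)

  # biases last, on draws after the survival pass
  if (bias$heaping_at_12m > 0) {
    heap <- died & death_age >= 10L & death_age <= 14L &
      runif(n_child) < bias$heaping_at_12m
    death_age[heap] <- 12L
  }
  keep_child <- rep(TRUE, n_child)
  if (bias$survivor_bias > 0) {
    d_per_woman <- tapply(died, woman_id, sum)
    p_remove <- 1 - (1 - bias$survivor_bias)^as.numeric(d_per_woman)
    removed_women <- as.integer(names(d_per_woman))[runif(length(d_per_woman)) < p_remove]
    keep_child <- !(woman_id %in% removed_women)
  }

  w <- if (design$weight_dispersion > 0) {
    sdlog <- sqrt(log1p(design$weight_dispersion^2))
    wt <- rlnorm(design$n_women, -sdlog^2 / 2, sdlog)
    wt / mean(wt)
  } else {
    rep(1, design$n_women)
  }

  out <- tibble(
    woman_id = woman_id,
    child_id = stats::ave(woman_id, woman_id, FUN = seq_along),
    dob_cmc = dob,
    died = died,
    death_age_months = death_age,
    interview_cmc = design$interview_cmc,
    weight = w[woman_id]
  )[keep_child, ]
  structure(out, class = c("u5_birth_records", class(out)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.u5_surface <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$age_month, y = .data$m,
                 group = .data$year, colour = .data$year)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (months)", y = "Annual death rate m[x]",
                  colour = "Year") +
    ggplot2::theme_minimal()
}
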