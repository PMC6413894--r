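#' Fit a Lee-Carter decomposition to a log-mortality surface
#'
#' Decomposes log death rates as `log m[x, t] = a_x + b_x * k_t + e_xt`:
#' `a_x` is the age-specific mean over observed years, and the first
#' singular triplet of the row-centered surface gives the age loadings
#' `b_x` and the period index `k_t`, rescaled to the usual normalization
#' `sum(b_x) = 1`, `sum(k_t) = 0`. Goodness of fit is reported as the share
#' of the centered surface's variation captured by the first singular
#' component, `ve = s1^2 / sum(s_j^2)`. Years whose column is entirely
#' missing are dropped, so the series may have gaps; at least three observed
#' years are required (the limited-data variant's minimum), and all 60 ages
#' must be present in every observed year.
#'
#' A constant surface (zero after centering) is degenerate: the fit returns
#' uniform `b`, `k = 0`, `ve = 1`, and sets the `degenerate` flag rather
#' than failing.
#'
#' @param logm A long tibble with columns `age_month`, `year`, and `log_m`
#'   (or `m`, which is logged), or a 60-row matrix with years as columns.
#' @return An object of class `u5_lc`: list with `a` (60), `b` (60,
#'   `sum(b) = 1`), `k` (named by observed year, `sum(k) = 0`), `e_sigma2`
#'   (mean squared residual), `ve`, `years`, `degenerate`.
#' @examples
#' surf <- make_true_surface(years = 1995:2017, seed = 7)
#' fit <- fit_lc(surf)
#' glance(fit)
#' @export
fit_lc <- function(logm) {
  if (is.data.frame(logm)) {
    if (!"log_m" %in% names(logm)) {
      if ("m" %in% names(logm)) {
        logm <- mutate(logm, log_m = log(.data$m))
      } else {
        abort("logm needs a `log_m` or `m` column")
      }
    }
    M <- surface_matrix(logm, "log_m")
  } else {
    M <- as.matrix(logm)
    if (is.null(colnames(M))) colnames(M) <- seq_len(ncol(M))
  }
  if (nrow(M) != 60L) abort("the surface must cover all 60 age months")
  observed <- colSums(is.na(M)) == 0
  gappy <- colSums(is.na(M)) > 0 & colSums(is.na(M)) < nrow(M)
  if (any(gappy)) {
    abort("years with partially missing ages cannot be fitted; drop or impute them")
  }
  M <- M[, observed, drop = FALSE]
  years <- as.numeric(colnames(M))
  if (ncol(M) < 3L) {
    abort("at least 3 observed years are required to fit the model")
  }

  a <- rowMeans(M)
  C <- M - a
  degenerate <- FALSE
  if (max(abs(C)) < 1e-12) {
    b <- rep(1 / 60, 60)
    k <- setNames(rep(0, ncol(M)), years)
    e_sigma2 <- 0
    ve <- 1
    degenerate <- TRUE
  } else {
    sv <- svd(C)
    u1 <- sv$u[, 1]; v1 <- sv$v[, 1]; s1 <- sv$d[1]
    if (sum(u1) < 0) { u1 <- -u1; v1 <- -v1 }   # sign: loadings sum positive
    b <- u1 / sum(u1)
    k <- setNames(s1 * v1 * sum(u1), years)     # row-centered => sum(k) = 0
    resid <- C - outer(b, k)
    e_sigma2 <- mean(resid^2)
    ve <- s1^2 / sum(sv$d^2)
  }
  structure(list(a = a, b = b, k = k, e_sigma2 = e_sigma2, ve = ve,
                 years = years, degenerate = degenerate),
            class = "u5_lc")
}

#' @export
print.u5_lc <- function(x, ...) {
  cat(sprintf("Lee-Carter fit: %d years (%s-%s%s), ve = %.3f%s\n",
              length(x$years), min(x$years), max(x$years),
              if (length(x$years) < diff(range(x$years)) + 1) ", gapped" else "",
              x$ve, if (x$degenerate) " [degenerate]" else ""))
  drift <- (tail(x$k, 1) - x$k[1]) / diff(range(x$years))
  cat(sprintf("  endpoint drift of k: %.3f per year; residual SD %.4f\n",
              drift, sqrt(x$e_sigma2)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.u5_lc <- function(x, ...) {
  bind_rows(
    tibble(term = "a", age_month = 0:59, year = NA_real_, estimate = x$a),
    tibble(term = "b", age_month = 0:59, year = NA_real_, estimate = x$b),
    tibble(term = "k", age_month = NA_integer_, year = x$years,
           estimate = unname(x$k))
  )
}

#' @exportS3Method generics::glance
glance.u5_lc <- function(x, ...) {
  tibble(n_years = length(x$years), ve = x$ve, e_sigma2 = x$e_sigma2,
         drift = unname((tail(x$k, 1) - x$k[1]) / diff(range(x$years))),
         degenerate = x$degenerate)
}

#' @exportS3Method ggplot2::autoplot
autoplot.u5_lc <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = ifelse(dat$term == "k", dat$year, dat$age_month),
    y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "age (months) / year", y = "estimate") +
    ggplot2::theme_minimal()
}

# drift and innovation variance of k under a random walk with drift,
# honouring unequal year spacing: endpoint drift, residual increments
# scaled by 1/sqrt(spacing)
k_drift_var <- function(k, years) {
  span <- diff(range(years))
  drift <- unname((k[length(k)] - k[1]) / span)
  h <- diff(years)
  d <- diff(k)
  resid <- (d - drift * h) / sqrt(h)
  n_inc <- length(d)
  sigma2 <- if (n_inc > 1) sum(resid^2) / (n_inc - 1) else 0
  list(drift = drift, sigma2 = sigma2, span = span,
       degenerate_var = sigma2 <= 0)
}

#' Forecast the period index by a random walk with drift
#'
#' The drift is the endpoint slope `(k_last - k_first) / (t_last -
#' t_first)` and the innovation variance is estimated from drift-adjusted
#' increments, each scaled by its year spacing, so the estimate is
#' invariant to gaps in the observed series. Three bound widths are
#' returned, built from nested variance components at horizon `h` years
#' past the last observed year:
#' \describe{
#'   \item{narrow}{process variance only, `sigma_k^2 * h`;}
#'   \item{unbiased}{adds drift-estimation variance
#'     `sigma_k^2 * h^2 / (t_last - t_first)`;}
#'   \item{wide}{adds the fitting-error term `e_sigma2 / sum(b^2)`, the
#'     `k`-scale variance implied by projecting the age-period residual
#'     onto the `b` direction.}
#' }
#' Intervals are Gaussian on the `k` scale at the given coverage.
#'
#' @param fit A [fit_lc()] object.
#' @param years Forecast years (each beyond the last observed year).
#' @param level Coverage level of the intervals (default 0.95).
#' @return A tibble with `year`, `bound` (narrow/unbiased/wide), `k`, `lo`,
#'   `hi`; `attr(, "drift")` and `attr(, "sigma2")` carry the random-walk
#'   estimates, and a degenerate (all-equal `k`) series is flagged in
#'   `attr(, "degenerate_var")`.
#' @export
forecast_k <- function(fit, years = c(2030, 2050), level = 0.95) {
  stopifnot(inherits(fit, "u5_lc"))
  t_last <- max(fit$years)
  if (any(years <= t_last)) {
    abort(sprintf("forecast years must lie beyond the last observed year (%d)",
                  t_last))
  }
  kv <- k_drift_var(fit$k, fit$years)
  if (kv$degenerate_var) {
    warn("period index has zero innovation variance; intervals are degenerate")
  }
  k_last <- unname(fit$k[length(fit$k)])
  z <- qnorm(1 - (1 - level) / 2)
  var_fit <- fit$e_sigma2 / sum(fit$b^2)
  out <- tidyr::expand_grid(year = years,
                            bound = c("narrow", "unbiased", "wide")) %>%
    mutate(
      h = .data$year - t_last,
      k = k_last + kv$drift * .data$h,
      var = kv$sigma2 * .data$h +
        ifelse(.data$bound %in% c("unbiased", "wide"),
               kv$sigma2 * .data$h^2 / kv$span, 0) +
        ifelse(.data$bound == "wide", var_fit, 0),
      lo = .data$k - z * sqrt(.data$var),
      hi = .data$k + z * sqrt(.data$var)
    ) %>%
    select("year", "bound", "k", "lo", "hi")
  structure(out, drift = kv$drift, sigma2 = kv$sigma2,
            degenerate_var = kv$degenerate_var)
}

#' Age profile and summary rates implied by a period-index value
#'
#' Inverts the decomposition: `m[x] = exp(a_x + b_x * k)`, then converts to
#' monthly probabilities and aggregates to NMR/IMR/U5MR.
#'
#' @param fit A [fit_lc()] object.
#' @param k A period-index value (scalar).
#' @return A list with `profile` (tibble `age_month`, `m`) and `rates`
#'   (one-row tibble of proportions from [summary_rates()]).
#' @export
mortality_from_fit <- function(fit, k) {
  stopifnot(inherits(fit, "u5_lc"), length(k) == 1)
  m <- exp(fit$a + fit$b * k)
  m_cap <- q_to_m(1 - 1e-9)
  lt <- life_table(m_to_q(pmin(m, m_cap)))
  list(profile = tibble(age_month = 0:59, m = m),
       rates = summary_rates(lt))
}

#' Forecast mortality rates with error bounds
#'
#' Combines [forecast_k()] with [mortality_from_fit()]: the point forecast
#' uses the median `k`, and interval bounds are obtained by transforming the
#' `k` interval endpoints through the (monotone in each age where `b_x > 0`)
#' rate mapping, taking the per-indicator min/max so bounds are valid even
#' if some loadings are slightly negative.
#'
#' @inheritParams forecast_k
#' @return A tibble with `year`, `bound`, and per indicator
#'   (`nmr`, `imr`, `u5mr`) the median and `_lo` / `_hi` bounds, all per
#'   1,000 live births.
#' @export
forecast_rates <- function(fit, years = c(2030, 2050), level = 0.95) {
  fk <- forecast_k(fit, years = years, level = level)
  out <- purrr::pmap_dfr(fk, function(year, bound, k, lo, hi) {
    r_med <- mortality_from_fit(fit, k)$rates
    r_a <- mortality_from_fit(fit, lo)$rates
    r_b <- mortality_from_fit(fit, hi)$rates
    tibble(
      year = year, bound = bound,
      nmr = 1000 * r_med$nmr,
      nmr_lo = 1000 * min(r_a$nmr, r_b$nmr),
      nmr_hi = 1000 * max(r_a$nmr, r_b$nmr),
      imr = 1000 * r_med$imr,
      imr_lo = 1000 * min(r_a$imr, r_b$imr),
      imr_hi = 1000 * max(r_a$imr, r_b$imr),
      u5mr = 1000 * r_med$u5mr,
      u5mr_lo = 1000 * min(r_a$u5mr, r_b$u5mr),
      u5mr_hi = 1000 * max(r_a$u5mr, r_b$u5mr)
    )
  })
  structure(out, class = c("u5_lc_forecast", class(out)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.u5_lc_forecast <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$year, y = .data$u5mr, colour = .data$bound)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$u5mr_lo, ymax = .data$u5mr_hi),
      position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = "Year", y = "U5MR per 1,000", colour = "Bound") +
    ggplot2::theme_minimal()
}
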