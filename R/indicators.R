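#' Total proportional decline between two rates
#'
#' `D = 1 - rate_end / rate_start`, a proportion (0.25 means the rate fell
#' by a quarter; negative values mean an increase). Invariant to rescaling
#' both rates by a common factor, so per-1,000 rates and proportions give
#' the same decline.
#'
#' @param rate_start,rate_end Rates at the start and end of the period (any
#'   common scale); `rate_start` must be positive.
#' @return The decline as a proportion (vectorized).
#' @examples
#' compute_decline(235, 55)  # 0.766
#' @export
compute_decline <- function(rate_start, rate_end) {
  if (any(rate_start <= 0)) abort("rate_start must be positive")
  1 - rate_end / rate_start
}

#' Annual rate of reduction implied by a total decline
#'
#' The constant yearly proportional decline equivalent to a total decline
#' `D` over `t` years: `ARR = 100 * (1 - (1 - D)^(1/t))`, in percent per
#' year. Equivalently `100 * (1 - (rate_end/rate_start)^(1/t))`.
#'
#' @param decline Total proportional decline (see [compute_decline()]);
#'   must be below 1.
#' @param years Period length in calendar years; must be positive.
#' @return ARR in percent per year (vectorized).
#' @examples
#' compute_arr(0.764, 27)  # 5.2 to one decimal
#' compute_arr(compute_decline(100, 50), 10)  # 6.70
#' @export
compute_arr <- function(decline, years) {
  if (any(decline >= 1)) abort("decline must be below 1 (rates cannot reach 0)")
  if (any(years <= 0)) abort("years must be positive")
  100 * (1 - (1 - decline)^(1 / years))
}

#' Decline and ARR summary for a period
#'
#' @param rate_start,rate_end Rates per 1,000 at the period endpoints.
#' @param years Period length in years.
#' @return A one-row tibble: `rate_start`, `rate_end`, `years`,
#'   `decline` (proportion), `arr` (percent per year).
#' @export
trend_summary <- function(rate_start, rate_end, years) {
  d <- compute_decline(rate_start, rate_end)
  tibble(rate_start = rate_start, rate_end = rate_end, years = years,
         decline = d, arr = compute_arr(d, years))
}

#' Classify countries against the SDG-3 mortality targets
#'
#' The SDG-3 targets are a neonatal mortality rate of at most 12 and an
#' under-5 mortality rate of at most 25 deaths per 1,000 live births by
#' 2030. A country is *on-track by 2030* if both its 2030 forecasts meet
#' their thresholds (inclusive); *between 2030 and 2050* if not, but both
#' 2050 forecasts do; otherwise *after 2050*. Missing forecasts give
#' *indeterminate*. By default the comparison uses median forecasts; set
#' `use = "upper"` for a conservative reading that requires the upper
#' interval bound to meet the thresholds.
#'
#' @param forecasts A tibble with one row per country and columns
#'   `country`, `nmr_2030`, `u5mr_2030`, `nmr_2050`, `u5mr_2050` (per
#'   1,000), and for `use = "upper"` the matching `_hi` columns.
#' @param use `"median"` (default) or `"upper"`.
#' @param nmr_target,u5mr_target Thresholds per 1,000 (defaults 12 and 25).
#' @return The input with an added `category` factor (`"on-track by
#'   2030"`, `"between 2030 and 2050"`, `"after 2050"`,
#'   `"indeterminate"`).
#' @examples
#' assess_sdg(tibble::tibble(country = "A", nmr_2030 = 10, u5mr_2030 = 22,
#'                           nmr_2050 = 8, u5mr_2050 = 15))
#' @export
assess_sdg <- function(forecasts, use = c("median", "upper"),
                       nmr_target = 12, u5mr_target = 25) {
  use <- match.arg(use)
  suffix <- if (use == "upper") "_hi" else ""
  col <- function(ind, yr) forecasts[[paste0(ind, "_", yr, suffix)]]
  need <- as.vector(outer(c("nmr", "u5mr"), c(2030, 2050),
                          function(i, y) paste0(i, "_", y, suffix)))
  if (!all(need %in% names(forecasts))) {
    abort(paste("forecasts must have columns:", paste(need, collapse = ", ")))
  }
  meets_2030 <- col("nmr", 2030) <= nmr_target & col("u5mr", 2030) <= u5mr_target
  meets_2050 <- col("nmr", 2050) <= nmr_target & col("u5mr", 2050) <= u5mr_target
  levels <- c("on-track by 2030", "between 2030 and 2050", "after 2050",
              "indeterminate")
  category <- case_when(
    is.na(meets_2030) | (!meets_2030 & is.na(meets_2050)) ~ levels[4],
    meets_2030 ~ levels[1],
    meets_2050 ~ levels[2],
    .default = levels[3]
  )
  mutate(forecasts, category = factor(category, levels = levels))
}
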