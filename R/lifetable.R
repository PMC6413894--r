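#' Convert annual death rates to monthly death probabilities and back
#'
#' With deaths uniformly distributed within each one-month age interval, an
#' annual central death rate `m` (deaths per person-year) implies a monthly
#' probability of dying `q = (m/12) / (1 + m/24)`; the inverse is
#' `m = 12 q / (1 - q/2)`. The conversion is exact, monotone, and satisfies
#' `q < m/12` for all `m > 0` (the probability lies below the central-rate
#' approximation) with `q -> m/12` as `m -> 0`. `q` reaches 1 at `m = 24`
#' deaths per person-year, so `m` must lie in `[0, 24)`.
#'
#' @param m Annual death rate(s), deaths per person-year, in `[0, 24)`.
#' @param q Monthly death probability(ies) in `[0, 1)`.
#' @return Numeric vector; `NA` values propagate.
#' @examples
#' m_to_q(0.12)          # 0.00995025
#' q_to_m(m_to_q(2.5))   # 2.5
#' @export
m_to_q <- function(m) {
  bad <- !is.na(m) & m < 0
  if (any(bad)) abort("annual rate `m` must be nonnegative")
  if (any(!is.na(m) & m >= 24)) {
    abort("annual rate `m` must be below 24 per person-year (q would reach 1)")
  }
  (m / 12) / (1 + m / 24)
}

#' @rdname m_to_q
#' @export
q_to_m <- function(q) {
  bad <- !is.na(q) & (q < 0 | q >= 1)
  if (any(bad)) abort("monthly probability `q` must be in [0, 1)")
  12 * q / (1 - q / 2)
}

#' Tabulate deaths and exposure by age month and calendar year
#'
#' Allocates each child's person-time and death to cells of a 60-month-age
#' by calendar-year grid. A child contributes one person-month of exposure
#' to cell `(x, t)` for every completed month `x` it lived whose calendar
#' month falls in year `t` inside the window; the month of death contributes
#' half a person-month and one death; the censoring (interview) month
#' contributes nothing; age months at or beyond 60 are ignored. A calendar
#' month is assigned to the year containing its first day. Records whose
#' reported death age implies a death after the interview are rejected and
#' counted in `attr(, "rejected")`.
#'
#' @param records A birth-record tibble as produced by
#'   [simulate_birth_histories()] (columns `woman_id`, `child_id`, `dob_cmc`,
#'   `died`, `death_age_months`, `interview_cmc`, optional `weight`).
#' @param window Inclusive calendar-year range `c(first, last)` to tabulate.
#'   Defaults to the 5 calendar years ending in the (latest) interview year.
#' @param weighted If `TRUE`, contributions are multiplied by the `weight`
#'   column (deaths become weighted counts). Default `FALSE`.
#' @return A tibble of class `u5_events` with columns `age_month`, `year`,
#'   `deaths`, `exposure` (person-months), covering the full grid of the
#'   window; `attr(, "rejected")` counts dropped records.
#' @examples
#' rec <- tibble::tibble(woman_id = 1, child_id = 1, dob_cmc = cmc(2000, 1),
#'                       died = TRUE, death_age_months = 3L,
#'                       interview_cmc = cmc(2001, 1), weight = 1)
#' ev <- tabulate_events(rec, window = c(2000, 2000))
#' sum(ev$deaths); sum(ev$exposure)  # 1 death, 3.5 person-months
#' @export
tabulate_events <- function(records, window = NULL, weighted = FALSE) {
  req <- c("dob_cmc", "died", "death_age_months", "interview_cmc")
  if (!all(req %in% names(records))) {
    abort(paste("records must have columns:", paste(req, collapse = ", ")))
  }
  if (is.null(window)) {
    yi <- max(cmc_year(records$interview_cmc))
    window <- c(yi - 4L, yi)
  }
  window <- as.integer(range(window))
  years <- seq(window[1], window[2])

  age_at_interview <- records$interview_cmc - records$dob_cmc
  bad <- records$died & !is.na(records$death_age_months) &
    records$death_age_months > age_at_interview
  rejected <- sum(bad)
  if (rejected > 0) {
    warn(sprintf("%d record(s) imply death after the interview; dropped", rejected))
    records <- records[!bad, ]
    age_at_interview <- age_at_interview[!bad]
  }

  w <- if (weighted && "weight" %in% names(records)) records$weight else rep(1, nrow(records))

  # full months lived at ages 0..59: alive -> min(age_at_interview, 60);
  # died at x_d -> min(x_d, 60) full months plus a half month at x_d if < 60
  full_months <- ifelse(records$died,
                        pmin(records$death_age_months, 60L),
                        pmin(age_at_interview, 60L))
  full_months <- pmax(full_months, 0L)

  n_cells <- 60L * length(years)
  cell_of <- function(x, yr) {
    ok <- yr >= window[1] & yr <= window[2]
    ifelse(ok, (match(yr, years) - 1L) * 60L + x + 1L, NA_integer_)
  }

  # expand full exposure months
  idx <- rep.int(seq_len(nrow(records)), full_months)
  x_full <- sequence(full_months) - 1L
  yr_full <- cmc_year(records$dob_cmc[idx] + x_full)
  cf <- cell_of(x_full, yr_full)
  keep <- !is.na(cf)
  E <- numeric(n_cells)
  tmp <- rowsum(w[idx][keep], cf[keep])
  E[as.integer(rownames(tmp))] <- tmp[, 1]

  # death month: half exposure + one death
  D <- numeric(n_cells)
  d <- which(records$died & records$death_age_months < 60L)
  if (length(d)) {
    xd <- records$death_age_months[d]
    yrd <- cmc_year(records$dob_cmc[d] + xd)
    cd <- cell_of(xd, yrd)
    keep <- !is.na(cd)
    if (any(keep)) {
      tmp <- rowsum(w[d][keep], cd[keep])
      E[as.integer(rownames(tmp))] <- E[as.integer(rownames(tmp))] + 0.5 * tmp[, 1]
      D[as.integer(rownames(tmp))] <- D[as.integer(rownames(tmp))] + tmp[, 1]
    }
  }

  out <- tibble(
    age_month = rep(0:59, times = length(years)),
    year = rep(years, each = 60L),
    deaths = D,
    exposure = E
  )
  structure(out, class = c("u5_events", class(out)), rejected = rejected)
}

#' Annualized death rates from tabulated events
#'
#' Computes `m[x, t] = deaths / (exposure / 12)` per cell, i.e. deaths per
#' person-year. Cells with zero exposure are flagged missing (`NA`), not
#' zero: downstream smoothing gives them zero weight.
#'
#' @param events A `u5_events` tibble from [tabulate_events()].
#' @return The events tibble with an added `m` column (class `u5_rates`).
#' @export
death_rates <- function(events) {
  out <- mutate(events,
    m = ifelse(.data$exposure > 0, .data$deaths / (.data$exposure / 12), NA_real_))
  structure(out, class = unique(c("u5_rates", class(out))))
}

#' Build a monthly life table from death probabilities
#'
#' @param q Monthly death probabilities for age months 0-59 (length 60), or
#'   a data frame with columns `age_month` and `q`.
#' @return A tibble of class `u5_life_table` with `age_month`, `q`,
#'   `p = 1 - q`, and cumulative survival `l` (`l[0] = 1`,
#'   `l[x] = prod_{u<x} p[u]`).
#' @export
life_table <- function(q) {
  if (is.data.frame(q)) {
    q <- q$q[order(q$age_month)]
  }
  if (length(q) != 60L) abort("a monthly life table needs exactly 60 ages (0-59)")
  if (any(is.na(q)) || any(q < 0) || any(q >= 1)) {
    abort("q must be in [0, 1) for all 60 ages")
  }
  p <- 1 - q
  out <- tibble(age_month = 0:59, q = q, p = p,
                l = c(1, cumprod(p))[1:60])
  structure(out, class = c("u5_life_table", class(out)))
}

#' Neonatal, infant, and under-5 mortality from a monthly life table
#'
#' `NMR = q[0]`, `IMR = 1 - prod(1 - q[0..11])`,
#' `U5MR = 1 - prod(1 - q[0..59])`; all returned as proportions (multiply by
#' 1,000 for the conventional per-1,000 scale). Nesting
#' `NMR <= IMR <= U5MR` holds by construction.
#'
#' @param lt A [life_table()], or a vector/data frame accepted by it.
#' @return A one-row tibble with `nmr`, `imr`, `u5mr` (proportions).
#' @examples
#' summary_rates(life_table(rep(0.002, 60)))
#' @export
summary_rates <- function(lt) {
  if (!inherits(lt, "u5_life_table")) lt <- life_table(lt)
  p <- lt$p[order(lt$age_month)]
  tibble(nmr = lt$q[lt$age_month == 0],
         imr = 1 - prod(p[1:12]),
         u5mr = 1 - prod(p[1:60]))
}

#' Per-year life tables and summary rates from a rate surface
#'
#' Convenience wrapper: converts each year's column of annualized rates to
#' monthly probabilities via [m_to_q()] and aggregates with
#' [summary_rates()]. Years with any missing rate (zero-exposure cells) are
#' silently dropped; rates at or above 24 per person-year -- possible in
#' pathologically sparse cells where a death carries only its own half month
#' of exposure -- are clamped just below the `q = 1` boundary.
#'
#' @param rates A long tibble with `age_month`, `year`, `m`.
#' @return A tibble with one row per complete year: `year`, `nmr`, `imr`,
#'   `u5mr` (proportions).
#' @export
annual_summary_rates <- function(rates) {
  m_cap <- q_to_m(1 - 1e-9)
  rates %>%
    group_by(.data$year) %>%
    filter(!any(is.na(.data$m)) && n() == 60L) %>%
    summarise(summary_rates(life_table(
      m_to_q(pmin(.data$m[order(.data$age_month)], m_cap)))),
      .groups = "drop")
}
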