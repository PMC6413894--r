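#' Survival probability over a standard age band
#'
#' The three calibration bands are neonatal (age month 0), postneonatal
#' (months 1-11), and child (months 12-59). The band survival is the product
#' of the monthly survival probabilities `p[x]` over the band.
#'
#' @param lt A [life_table()].
#' @param band One of `"neonatal"`, `"postneonatal"`, `"child"`.
#' @return A probability in `[0, 1]`.
#' @examples
#' lt <- life_table(rep(0.001, 60))
#' band_survival(lt, "child")  # 0.999^48
#' @export
band_survival <- function(lt, band = c("neonatal", "postneonatal", "child")) {
  band <- match.arg(band)
  ages <- band_ages(band)
  p <- lt$p[order(lt$age_month)]
  prod(p[ages + 1L])
}

band_ages <- function(band) {
  switch(band,
    neonatal = 0L,
    postneonatal = 1:11,
    child = 12:59
  )
}

#' Calibrate a monthly life table to external summary rates
#'
#' Adjusts the monthly survival probabilities proportionally within the
#' neonatal, postneonatal, and child age bands so that the recomputed NMR,
#' IMR, and U5MR match external target values exactly. For each band the
#' adjustment factor is the ratio of the target band survival to the
#' observed one, `f_M = S*_band / S_band`, where the target band survivals
#' are `1 - nmr*`, `(1 - imr*)/(1 - nmr*)`, and `(1 - u5mr*)/(1 - imr*)`.
#' The band factor is spread uniformly on the log-survival scale: each of
#' the band's `w` monthly `p` values is multiplied by `f_M^(1/w)`, which
#' preserves the within-band age shape. If an adjusted `p` would reach 1 it
#' is capped at `1 - 1e-9` and the remaining factor is redistributed over
#' the band's other months (the result is flagged). The measurement error
#' per band is `d_M = 1 - f_M`.
#'
#' @param lt A [life_table()] of observed monthly probabilities.
#' @param targets A one-row data frame (or named list) with `nmr`, `imr`,
#'   `u5mr` as proportions satisfying `0 < nmr <= imr <= u5mr < 1`.
#' @return A list of class `u5_calibration`: `life_table` (the calibrated
#'   [life_table()]), `factors` (tibble with `band`, `f`, `d`, `capped`),
#'   and `rates` (recomputed summary rates, equal to the targets).
#' @examples
#' lt <- life_table(rep(0.002, 60))
#' cal <- calibrate_to_targets(lt, list(nmr = 0.03, imr = 0.05, u5mr = 0.09))
#' cal$factors
#' @export
calibrate_to_targets <- function(lt, targets) {
  stopifnot(inherits(lt, "u5_life_table"))
  tg <- as.list(targets)[c("nmr", "imr", "u5mr")]
  if (any(vapply(tg, is.null, logical(1)))) {
    abort("targets must provide nmr, imr, u5mr")
  }
  nmr <- tg$nmr; imr <- tg$imr; u5mr <- tg$u5mr
  if (!(0 < nmr && nmr <= imr && imr <= u5mr && u5mr < 1)) {
    abort("targets must satisfy 0 < nmr <= imr <= u5mr < 1")
  }

  s_target <- c(neonatal = 1 - nmr,
                postneonatal = (1 - imr) / (1 - nmr),
                child = (1 - u5mr) / (1 - imr))
  p <- lt$p[order(lt$age_month)]
  bands <- c("neonatal", "postneonatal", "child")
  fac <- tibble(band = bands, f = NA_real_, d = NA_real_, capped = FALSE)

  for (i in seq_along(bands)) {
    ages <- band_ages(bands[i]) + 1L
    s_obs <- prod(p[ages])
    if (s_obs <= 0) {
      abort(sprintf("cannot calibrate: observed %s band survival is 0", bands[i]))
    }
    f <- s_target[[bands[i]]] / s_obs
    fac$f[i] <- f
    fac$d[i] <- 1 - f
    # spread f over the band on the log scale, capping p just below 1
    free <- rep(TRUE, length(ages))
    p_new <- p[ages]
    remaining <- s_target[[bands[i]]]
    repeat {
      g <- (remaining / prod(p_new[free]))^(1 / sum(free))
      cand <- p_new
      cand[free] <- p_new[free] * g
      over <- free & cand >= 1
      if (!any(over)) {
        p_new <- cand
        break
      }
      fac$capped[i] <- TRUE
      p_new[over] <- 1 - 1e-9
      free <- free & !over
      remaining <- s_target[[bands[i]]] / prod(p_new[!free])
      if (!any(free)) {
        abort(sprintf("cannot calibrate: %s band cannot reach its target survival",
                      bands[i]))
      }
    }
    p[ages] <- p_new
  }

  lt_cal <- life_table(1 - p)
  structure(list(life_table = lt_cal,
                 factors = fac,
                 rates = summary_rates(lt_cal)),
            class = "u5_calibration")
}

#' @export
print.u5_calibration <- function(x, ...) {
  cat("Calibrated under-5 life table\n")
  cat("Band adjustment factors (d = 1 - f):\n")
  print(as.data.frame(x$factors), row.names = FALSE)
  cat(sprintf("Calibrated rates (per 1,000): NMR %.1f, IMR %.1f, U5MR %.1f\n",
              1000 * x$rates$nmr, 1000 * x$rates$imr, 1000 * x$rates$u5mr))
  invisible(x)
}

#' Read external calibration/target rates from CSV
#'
#' Expects columns `country`, `year`, `nmr`, `imr`, `u5mr` and optionally
#' 90% interval bounds `<indicator>_lower` / `<indicator>_upper`. Rates are
#' given per 1,000 live births (the conventional reporting scale) and
#' converted to proportions on read.
#'
#' @param path CSV file path.
#' @param per_1000 If `TRUE` (default), rate columns are divided by 1,000.
#' @return A tibble with rates as proportions.
#' @export
read_calibration_targets <- function(path, per_1000 = TRUE) {
  tg <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("country", "year", "nmr", "imr", "u5mr")
  if (!all(need %in% names(tg))) {
    abort(paste("targets file must have columns:", paste(need, collapse = ", ")))
  }
  if (per_1000) {
    rate_cols <- setdiff(names(tg), c("country", "year"))
    tg <- mutate(tg, across(dplyr::all_of(rate_cols), ~ .x / 1000))
  }
  tg
}
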