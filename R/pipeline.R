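#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]: the ground-truth
#' surface, the survey design and reporting biases, the estimation window,
#' smoothing, forecasting, and assessment choices. All randomness flows from
#' the single `seed` via fixed per-stage offsets, so stages are individually
#' re-runnable and a full run is reproducible end to end.
#'
#' @param country Label used in output tables.
#' @param years Calendar years of the true surface (and estimation window).
#' @param surface Named list of overrides for [make_true_surface()]
#'   (e.g. `list(k_sigma = 0, e_sigma = 0)`).
#' @param design A [survey_design()].
#' @param bias A [bias_config()].
#' @param weighted Use sampling weights in tabulation (default `FALSE`).
#' @param targets Optional calibration targets: a tibble as returned by
#'   [read_calibration_targets()], or a CSV path, or `NULL` to skip
#'   calibration.
#' @param lambda P-spline smoothing parameter pair, or `NULL` for BIC
#'   selection.
#' @param forecast_years Horizon years (default 2030 and 2050).
#' @param bound Bound type used for assessment intervals
#'   (`"unbiased"`, `"narrow"`, `"wide"`).
#' @param assess_use `"median"` or `"upper"`; see [assess_sdg()].
#' @param level Interval coverage (default 0.95).
#' @param seed Root seed for the run.
#' @return A list of class `u5_config`.
#' @export
pipeline_config <- function(country = "SYNTHETIC",
                            years = 1993:2017,
                            surface = list(),
                            design = survey_design(),
                            bias = bias_config(),
                            weighted = FALSE,
                            targets = NULL,
                            lambda = NULL,
                            forecast_years = c(2030, 2050),
                            bound = c("unbiased", "narrow", "wide"),
                            assess_use = c("median", "upper"),
                            level = 0.95,
                            seed = 1L) {
  structure(list(country = country, years = years, surface = surface,
                 design = design, bias = bias, weighted = weighted,
                 targets = targets, lambda = lambda,
                 forecast_years = forecast_years,
                 bound = match.arg(bound), assess_use = match.arg(assess_use),
                 level = level, seed = as.integer(seed)),
            class = "u5_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `design` and `bias` keys take the fields of [survey_design()] and
#' [bias_config()].
#'
#' @param path YAML file path.
#' @return A `u5_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("country", "weighted", "targets", "lambda",
                                  "forecast_years", "bound", "assess_use",
                                  "level", "seed", "surface"))]
  if (!is.null(y$years)) args$years <- seq(y$years[[1]], y$years[[length(y$years)]])
  if (!is.null(y$design)) args$design <- do.call(survey_design, y$design)
  if (!is.null(y$bias)) args$bias <- do.call(bias_config, y$bias)
  do.call(pipeline_config, args)
}

stage_seed <- function(seed, offset) (as.integer(seed) %% 1000000L) * 1000L + offset

#' Run the full estimation-to-assessment pipeline
#'
#' Executes, in order: simulate (ground-truth surface and birth histories),
#' estimate (tabulation and raw rates), calibrate (proportional band
#' adjustment to external targets, skipped with a warning if no targets are
#' supplied), smooth (2-D P-spline on the calibrated surface), fit
#' (Lee-Carter), forecast (2030/2050 with three bound widths), assess
#' (SDG-3 classification), and coverage (share of fitted rates inside the
#' targets' external intervals, when bounds are supplied). Every stage
#' writes its outputs as CSV into `outdir` together with a `run.log`
#' recording all flags raised (calibration caps, degeneracies,
#' non-convergence). Identical config and seed give byte-identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param seed Root seed; defaults to `config$seed`.
#' @return (Invisibly) a named list with every stage's result.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("u5run"),
                         seed = config$seed) {
  stopifnot(inherits(config, "u5_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  put <- function(x, name) readr::write_csv(x, file.path(outdir, name))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(err) {
      writeLines(c(log_lines, sprintf("stage %s FAILED: %s", name,
                                      conditionMessage(err))), log_path)
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(err)))
    })
  }

  # -- simulate ---------------------------------------------------------
  res <- list()
  res$surface <- run_stage("simulate", {
    args <- utils::modifyList(
      list(years = config$years, seed = stage_seed(seed, 1L)), config$surface)
    do.call(make_true_surface, args)
  })
  res$records <- run_stage("simulate", simulate_birth_histories(
    res$surface, config$design, config$bias, seed = stage_seed(seed, 2L)))
  put(res$surface, "true_surface.csv")
  put(res$records, "birth_records.csv")
  say("simulate: %d children from %d women; %d deaths",
      nrow(res$records), config$design$n_women, sum(res$records$died))

  # -- estimate ---------------------------------------------------------
  res$events <- run_stage("estimate", tabulate_events(
    res$records, window = range(config$years), weighted = config$weighted))
  res$rates <- death_rates(res$events)
  put(res$events, "events.csv")
  put(res$rates, "rates.csv")
  res$raw_summary <- annual_summary_rates(res$rates)
  put(res$raw_summary, "summary_raw.csv")
  say("estimate: %d cells, %d with zero exposure; %d record(s) rejected",
      nrow(res$events), sum(res$events$exposure == 0),
      attr(res$events, "rejected"))

  # -- calibrate --------------------------------------------------------
  targets <- config$targets
  if (is.character(targets)) targets <- read_calibration_targets(targets)
  m_cap <- q_to_m(1 - 1e-9)
  if (is.null(targets)) {
    warn("no calibration targets supplied; downstream stages use raw rates")
    say("calibrate: skipped (no targets); using raw rates")
    res$calibrated <- res$rates %>% select("age_month", "year", "m")
    res$calibration <- NULL
  } else {
    res$calibration <- run_stage("calibrate", {
      purrr::map_dfr(sort(unique(res$rates$year)), function(yr) {
        mr <- filter(res$rates, .data$year == yr)
        tg <- filter(targets, .data$year == yr)
        if (nrow(tg) == 0 || any(is.na(mr$m))) {
          say("calibrate: year %d left uncalibrated (%s)", yr,
              if (nrow(tg) == 0) "no target" else "missing cells")
          return(tibble(year = yr, band = NA_character_, f = NA_real_,
                        d = NA_real_, capped = NA, calibrated = FALSE))
        }
        lt <- life_table(m_to_q(pmin(mr$m[order(mr$age_month)], m_cap)))
        cal <- calibrate_to_targets(lt, tg[1, ])
        if (any(cal$factors$capped)) {
          say("calibrate: year %d capped p at 1 in band(s) %s", yr,
              paste(cal$factors$band[cal$factors$capped], collapse = ", "))
        }
        mutate(cal$factors, year = yr, calibrated = TRUE,
               .before = 1)
      })
    })
    put(res$calibration, "calibration_factors.csv")
    cal_years <- unique(res$calibration$year[res$calibration$calibrated])
    res$calibrated <- purrr::map_dfr(sort(unique(res$rates$year)), function(yr) {
      mr <- filter(res$rates, .data$year == yr) %>% arrange(.data$age_month)
      if (yr %in% cal_years) {
        lt <- life_table(m_to_q(pmin(mr$m, m_cap)))
        cal <- calibrate_to_targets(lt, filter(targets, .data$year == yr)[1, ])
        tibble(age_month = 0:59, year = yr, m = q_to_m(cal$life_table$q))
      } else {
        tibble(age_month = 0:59, year = yr, m = mr$m)
      }
    })
    say("calibrate: %d/%d years calibrated", length(cal_years),
        length(unique(res$rates$year)))
  }
  put(res$calibrated, "calibrated_rates.csv")

  # -- smooth -----------------------------------------------------------
  res$smooth <- run_stage("smooth", {
    Em <- surface_matrix(res$events, "exposure")
    Mm <- surface_matrix(res$calibrated, "m")
    Dm <- Mm * Em / 12          # expected deaths at the calibrated rates
    Dm[is.na(Dm) | Em == 0] <- 0
    fit_pspline(list(D = Dm, E = Em), lambda = config$lambda)
  })
  smooth_long <- res$smooth$fitted %>%
    mutate(age_month = rep(0:59, times = length(unique(.data$year))),
           year = sort(unique(res$calibrated$year))[
             rep(seq_along(unique(.data$year)), each = 60L)])
  put(smooth_long, "smoothed_rates.csv")
  say("smooth: lambda = %s, effective dimension %.1f%s",
      paste(signif(res$smooth$lambda, 3), collapse = " x "), res$smooth$ed,
      if (res$smooth$converged) "" else " [NOT CONVERGED]")

  # -- fit --------------------------------------------------------------
  res$lc <- run_stage("fit", fit_lc(
    mutate(smooth_long, log_m = .data$log_m)))
  # variance explained is also reported for the calibrated, pre-smoothing
  # surface, the scale on which goodness of fit is usually quoted
  ve_cal <- tryCatch({
    L <- log(surface_matrix(res$calibrated, "m"))
    L[, colSums(!is.finite(L)) > 0] <- NA    # complete finite years only
    fit_lc(L)$ve
  }, error = function(err) NA_real_)
  res$ve <- tibble(ve_smoothed = res$lc$ve, ve_calibrated = ve_cal)
  put(tidy(res$lc), "lc_fit.csv")
  put(res$ve, "lc_ve.csv")
  if (res$lc$degenerate) say("fit: degenerate (constant) surface flagged")
  say("fit: ve %.3f (smoothed), %.3f (calibrated); drift %.3f/yr",
      res$lc$ve, ve_cal, attr(forecast_k(res$lc, max(config$years) + 1), "drift"))

  # -- forecast ---------------------------------------------------------
  res$forecast <- run_stage("forecast", forecast_rates(
    res$lc, years = config$forecast_years, level = config$level))
  put(res$forecast, "forecast_rates.csv")

  # -- assess -----------------------------------------------------------
  res$assessment <- run_stage("assess", {
    fb <- filter(res$forecast, .data$bound == config$bound)
    wide <- tibble(country = config$country)
    for (yr in c(2030, 2050)) {
      row <- filter(fb, .data$year == yr)
      for (ind in c("nmr", "u5mr")) {
        wide[[paste0(ind, "_", yr)]] <-
          if (nrow(row)) row[[ind]] else NA_real_
        wide[[paste0(ind, "_", yr, "_hi")]] <-
          if (nrow(row)) row[[paste0(ind, "_hi")]] else NA_real_
      }
    }
    trend <- trend_summary(
      rate_start = 1000 * res$raw_summary$u5mr[1],
      rate_end = 1000 * tail(res$raw_summary$u5mr, 1),
      years = diff(range(res$raw_summary$year)))
    cbind(wide, rename(trend, u5mr_decline = "decline", u5mr_arr = "arr")) %>%
      as_tibble() %>%
      assess_sdg(use = config$assess_use)
  })
  put(res$assessment, "assessment.csv")
  say("assess: %s -> %s", config$country, as.character(res$assessment$category))

  # -- coverage ---------------------------------------------------------
  if (!is.null(targets) &&
      any(grepl("_lower$", names(targets)))) {
    res$coverage <- run_stage("coverage", {
      est <- purrr::map_dfr(seq_along(res$lc$years), function(i) {
        r <- mortality_from_fit(res$lc, unname(res$lc$k[i]))$rates
        tibble(country = config$country, year = res$lc$years[i],
               indicator = c("nmr", "imr", "u5mr"),
               value = 1000 * c(r$nmr, r$imr, r$u5mr))
      })
      iv <- targets_intervals(targets, country = config$country)
      coverage_check(est, iv)
    })
    put(res$coverage, "coverage.csv")
  }

  writeLines(log_lines, log_path)
  res$outdir <- outdir
  invisible(res)
}

#' Reshape a wide targets table into long external intervals
#'
#' @param targets A targets tibble (proportions) with `<indicator>_lower` /
#'   `<indicator>_upper` columns.
#' @param country Country label to fill in when the table has none.
#' @return A tibble `country`, `year`, `indicator`, `lower`, `upper` per
#'   1,000 live births.
#' @export
targets_intervals <- function(targets, country = "SYNTHETIC") {
  if (!"country" %in% names(targets)) targets$country <- country
  purrr::map_dfr(c("nmr", "imr", "u5mr"), function(ind) {
    lo <- paste0(ind, "_lower"); hi <- paste0(ind, "_upper")
    if (!all(c(lo, hi) %in% names(targets))) return(tibble())
    tibble(country = targets$country, year = targets$year, indicator = ind,
           lower = 1000 * targets[[lo]], upper = 1000 * targets[[hi]])
  })
}

#' Share of estimates inside external interval bounds
#'
#' Matches point estimates to external (e.g. 90% credible) intervals by
#' country, year, and indicator, and reports per indicator the share of
#' matched estimates falling inside the bounds (inclusive).
#'
#' @param estimates Tibble with `country`, `year`, `indicator`, `value`.
#' @param intervals Tibble with `country`, `year`, `indicator`, `lower`,
#'   `upper` on the same scale as `value`.
#' @return A tibble of class `u5_coverage`: `indicator`, `n` matched,
#'   `inside`, `share`. With no matched rows, a zero-row result is returned
#'   with a warning.
#' @examples
#' est <- tibble::tibble(country = "A", year = 1:4, indicator = "nmr",
#'                       value = c(10, 20, 30, 40))
#' iv <- tibble::tibble(country = "A", year = 1:4, indicator = "nmr",
#'                      lower = 15, upper = 35)
#' coverage_check(est, iv)$share  # 0.5
#' @export
coverage_check <- function(estimates, intervals) {
  matched <- dplyr::inner_join(estimates, intervals,
                               by = c("country", "year", "indicator"))
  if (nrow(matched) == 0) {
    warn("no matched country-years between estimates and intervals")
    return(structure(tibble(indicator = character(), n = integer(),
                            inside = integer(), share = numeric()),
                     class = c("u5_coverage", class(tibble()))))
  }
  out <- matched %>%
    group_by(.data$indicator) %>%
    summarise(n = n(),
              inside = sum(.data$value >= .data$lower &
                             .data$value <= .data$upper),
              share = .data$inside / .data$n,
              .groups = "drop")
  structure(out, class = unique(c("u5_coverage", class(out))))
}
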