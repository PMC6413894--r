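make_normalized_abk <- function(years, seed = 1) {
  set.seed(seed)
  a <- default_age_baseline()
  b <- default_age_loadings()
  k <- cumsum(rnorm(length(years), -1.5, 0.3))
  k <- k - mean(k)
  list(a = a, b = b, k = k)
}

test_that("an exact rank-1 surface is recovered with ve = 1", {
  years <- 1995:2017
  p <- make_normalized_abk(years, seed = 41)
  M <- rank1_logm(p$a, p$b, p$k, years)
  fit <- fit_lc(M)
  expect_equal(fit$ve, 1, tolerance = 1e-12)
  expect_equal(fit$a, p$a, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$b, p$b, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(fit$k), p$k, tolerance = 1e-10)
  expect_equal(fit$e_sigma2, 0, tolerance = 1e-18)
  # normalization holds exactly
  expect_lt(abs(sum(fit$b) - 1), 1e-10)
  expect_lt(abs(sum(fit$k)), 1e-10)
  # round trip through the inverse map reproduces the surface
  recon <- sapply(fit$k, function(k) log(mortality_from_fit(fit, k)$profile$m))
  expect_lt(max(abs(recon - M)), 1e-10)
})

test_that("rescaled generating parameters give the identical normalized fit", {
  years <- 2000:2012
  p <- make_normalized_abk(years, seed = 42)
  M1 <- rank1_logm(p$a, p$b, p$k, years)
  M2 <- rank1_logm(p$a, p$b / 4, 4 * p$k, years)
  f1 <- fit_lc(M1); f2 <- fit_lc(M2)
  expect_equal(f1$b, f2$b, tolerance = 1e-10)
  expect_equal(f1$k, f2$k, tolerance = 1e-10)
})

test_that("a constant surface is flagged degenerate instead of failing", {
  M <- matrix(rep(default_age_baseline(), 5), nrow = 60,
              dimnames = list(NULL, 2001:2005))
  fit <- fit_lc(M)
  expect_true(fit$degenerate)
  expect_equal(fit$ve, 1)
  expect_equal(unname(fit$k), rep(0, 5))
  expect_equal(fit$b, rep(1 / 60, 60))
  expect_warning(forecast_k(fit, 2010), "zero innovation variance")
})

test_that("too few observed years is an explicit failure", {
  years <- 2001:2002
  p <- make_normalized_abk(years, seed = 43)
  expect_error(fit_lc(rank1_logm(p$a, p$b, p$k, years)), "3 observed years")
})

test_that("gapped years use true spacings and match the RW-drift ML oracle", {
  years <- c(1995, 1998, 1999, 2004, 2006, 2011, 2017)
  set.seed(44)
  h <- diff(years)
  k <- cumsum(c(0, -0.9 * h + rnorm(length(h), 0, sqrt(h) * 0.4)))
  k <- k - mean(k)
  p <- make_normalized_abk(years, seed = 44)
  fit <- fit_lc(rank1_logm(p$a, p$b, k - mean(k), years))
  fk <- forecast_k(fit, years = 2020)
  # ML for a RW with drift on unequal spacings, by direct optimization
  nll <- function(par) {
    d <- diff(unname(fit$k))
    sum(0.5 * log(2 * pi * par[2]^2 * h) + (d - par[1] * h)^2 / (2 * par[2]^2 * h))
  }
  ml <- optim(c(-1, 0.5), nll, method = "L-BFGS-B",
              lower = c(-5, 1e-4), upper = c(5, 5))$par
  expect_equal(attr(fk, "drift"), ml[1], tolerance = 1e-4)
  # endpoint drift equals the closed-form ML drift for this model
  expect_equal(attr(fk, "drift"),
               unname((fit$k[7] - fit$k[1]) / (2017 - 1995)), tolerance = 1e-12)
  # variance estimate close to ML (ML divides by n, ours by n-1)
  expect_equal(attr(fk, "sigma2") * (length(h) - 1) / length(h), ml[2]^2,
               tolerance = 1e-3)
  # invariance to re-indexing: shifting all years leaves drift unchanged
  fit2 <- fit_lc(rank1_logm(p$a, p$b, k - mean(k), years + 3))
  expect_equal(attr(forecast_k(fit2, 2021), "drift"), attr(fk, "drift"),
               tolerance = 1e-12)
})

test_that("an exactly linear index forecasts on the line with sqrt-h narrow widths", {
  years <- 2000:2012
  p <- make_normalized_abk(years, seed = 45)
  k_lin <- seq(-6, 6, by = 1)
  fit <- fit_lc(rank1_logm(p$a, p$b, k_lin, years))
  fk <- suppressWarnings(forecast_k(fit, years = c(2013, 2020)))
  expect_equal(fk$k[fk$year == 2013][1], 7, tolerance = 1e-8)
  expect_equal(fk$k[fk$year == 2020][1], 14, tolerance = 1e-8)
  # noisy index: narrow width scales as sqrt(horizon)
  set.seed(46)
  kn <- cumsum(rnorm(13, -1, 0.3)); kn <- kn - mean(kn)
  fitn <- fit_lc(rank1_logm(p$a, p$b, kn, years))
  fkn <- forecast_k(fitn, years = c(2013, 2016, 2021))
  nw <- with(fkn[fkn$bound == "narrow", ], hi - lo)
  expect_equal(nw[2] / nw[1], 2, tolerance = 1e-8)   # h = 4 vs 1
  expect_equal(nw[3] / nw[1], 3, tolerance = 1e-8)   # h = 9 vs 1
})

test_that("bound widths are nested narrow <= unbiased <= wide at every horizon", {
  surf <- make_true_surface(years = 1993:2017, seed = 47)
  fit <- fit_lc(surf)
  fk <- forecast_k(fit, years = c(2020, 2030, 2040, 2050))
  w <- tidyr::pivot_wider(
    dplyr::mutate(fk, width = hi - lo)[c("year", "bound", "width")],
    names_from = "bound", values_from = "width")
  expect_true(all(w$narrow <= w$unbiased + 1e-12))
  expect_true(all(w$unbiased <= w$wide + 1e-12))
  # widths grow with horizon for a fixed bound type
  expect_true(all(diff(w$narrow) > 0) && all(diff(w$wide) > 0))
  expect_error(forecast_k(fit, years = 2017), "beyond")
})

test_that("the inverse map is monotone in k and reduces to exp(a) at k = 0", {
  surf <- make_true_surface(years = 1993:2017, seed = 48)
  fit <- fit_lc(surf)
  expect_equal(mortality_from_fit(fit, 0)$profile$m, exp(fit$a),
               tolerance = 1e-12, ignore_attr = TRUE)
  m_hi <- mortality_from_fit(fit, 1)$profile$m
  m_lo <- mortality_from_fit(fit, -1)$profile$m
  expect_true(all(m_lo[fit$b > 0] < m_hi[fit$b > 0]))
  fr <- forecast_rates(fit, years = 2030)
  expect_true(all(fr$nmr_lo <= fr$nmr & fr$nmr <= fr$nmr_hi))
  expect_true(all(fr$u5mr_lo <= fr$u5mr & fr$u5mr <= fr$u5mr_hi))
})

test_that("drift is recovered within 10% over repeated simulated surfaces", {
  errs <- vapply(1:20, function(s) {
    surf <- make_true_surface(years = 1993:2017, seed = 400 + s)
    fit <- fit_lc(surf)
    abs(attr(forecast_k(fit, 2020), "drift") - (-1.8)) / 1.8
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("tidy and glance expose the decomposition in standard form", {
  surf <- make_true_surface(years = 1993:2017, seed = 49)
  fit <- fit_lc(surf)
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("a", "b", "k"))
  expect_equal(nrow(td), 60 + 60 + 25)
  gl <- glance(fit)
  expect_true(all(c("ve", "e_sigma2", "drift", "degenerate") %in% names(gl)))
  expect_true(gl$ve >= 0 && gl$ve <= 1)
})
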