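test_that("noise-free surface is exactly log-linear in time with slope b_x * drift", {
  d <- -0.12
  surf <- make_true_surface(years = 2000:2009, k_drift = d, k_sigma = 0,
                            e_sigma = 0, seed = 1)
  M <- log(surface_matrix(surf))
  b <- attr(surf, "truth")$b_x
  for (x in c(1, 17, 60)) {
    slopes <- diff(M[x, ])
    expect_equal(slopes, rep(b[x] * d, 9), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # k anchored: mean log m over years equals a_x exactly
  expect_equal(rowMeans(M), attr(surf, "truth")$a_x, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("an age with zero loading has a constant rate over years", {
  b <- c(0, rep(1 / 59, 59))
  surf <- make_true_surface(years = 2000:2009, b_x = b, k_sigma = 0,
                            e_sigma = 0, seed = 2)
  M <- surface_matrix(surf)
  expect_equal(M[1, ], rep(M[1, 1], 10), ignore_attr = TRUE)
  expect_gt(max(M[2, ]) / min(M[2, ]), 1)  # loaded ages do move
})

test_that("surface generation is reproducible under a fixed seed and rejects bad fields", {
  s1 <- make_true_surface(years = 2000:2005, seed = 7)
  s2 <- make_true_surface(years = 2000:2005, seed = 7)
  expect_identical(s1$m, s2$m)
  expect_error(make_true_surface(k_drift = NaN), "k_drift")
  expect_error(make_true_surface(b_x = rep(-1 / 60, 60)), "b_x")
  expect_error(make_true_surface(a_x = rep(Inf, 60)), "a_x")
})

test_that("a zero surface produces no deaths and heaping rewrites 10-14m deaths to 12", {
  years <- 2010:2017
  zero <- tibble::tibble(age_month = rep(0:59, length(years)),
                         year = rep(years, each = 60L), m = 0)
  rec <- simulate_birth_histories(zero, survey_design(n_women = 300,
                                                      window_years = 8),
                                  seed = 3)
  expect_false(any(rec$died))
  expect_true(all(is.na(rec$death_age_months)))

  surf <- const_q_surface(0.03, 1993:2017)
  rec2 <- simulate_birth_histories(surf, survey_design(n_women = 800),
                                   bias_config(heaping_at_12m = 1), seed = 4)
  aged <- rec2$death_age_months[rec2$died]
  expect_false(any(aged %in% c(10, 11, 13, 14)))
  expect_true(any(aged == 12))
})

test_that("month-0 death fraction matches the binomial oracle at constant q", {
  q <- 0.01
  surf <- const_q_surface(q, 1993:2017)
  rec <- simulate_birth_histories(surf, survey_design(n_women = 4000,
                                                      fertility_mean = 4),
                                  seed = 5)
  # children observed for at least one completed month
  obs <- rec[rec$interview_cmc - rec$dob_cmc >= 1, ]
  n <- nrow(obs)
  expect_gt(n, 10000)
  frac <- mean(obs$died & obs$death_age_months == 0)
  expect_lt(abs(frac - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("simulation rejects a window that starts before the surface", {
  surf <- const_q_surface(0.01, 2010:2017)
  expect_error(
    simulate_birth_histories(surf, survey_design(window_years = 20)),
    "window"
  )
})

test_that("tabulated estimates recover the true rates within Monte-Carlo error", {
  q <- 0.008
  surf <- const_q_surface(q, 1993:2017)
  m_true <- q_to_m(q)
  rec <- simulate_birth_histories(surf, survey_design(n_women = 6000,
                                                      fertility_mean = 5),
                                  seed = 6)
  ev <- tabulate_events(rec, window = c(1993, 2017))
  pooled <- dplyr::summarise(dplyr::group_by(ev, age_month),
                             D = sum(deaths), E = sum(exposure))
  m_hat <- pooled$D / (pooled$E / 12)
  se <- sqrt(pooled$D) / (pooled$E / 12)        # Poisson approximation
  expect_true(all(abs(m_hat - m_true) < 3 * pmax(se, 1e-6) |
                    (pooled$D == 0 & pooled$E < 1000)))
  # the overwhelming majority of ages must be well inside the band
  expect_gt(mean(abs(m_hat - m_true) < 3 * se), 0.9)
})

test_that("event counts are invariant to record order", {
  surf <- const_q_surface(0.02, 1993:2017)
  rec <- simulate_birth_histories(surf, survey_design(n_women = 500), seed = 8)
  ev1 <- tabulate_events(rec, window = c(1995, 2017))
  set.seed(1)
  ev2 <- tabulate_events(rec[sample(nrow(rec)), ], window = c(1995, 2017))
  expect_equal(ev1$deaths, ev2$deaths)
  expect_equal(ev1$exposure, ev2$exposure)
})

test_that("survivor bias strictly lowers the estimated U5MR on the same seed stream", {
  surf <- const_q_surface(0.015, 1993:2017)
  d <- survey_design(n_women = 3000)
  rec0 <- simulate_birth_histories(surf, d, bias_config(survivor_bias = 0),
                                   seed = 9)
  rec1 <- simulate_birth_histories(surf, d, bias_config(survivor_bias = 0.6),
                                   seed = 9)
  # identical pre-bias stream: biased run is a subset of the unbiased one
  expect_lt(nrow(rec1), nrow(rec0))
  u5 <- function(r) {
    ev <- death_rates(tabulate_events(r, window = c(1993, 2017)))
    pooled <- dplyr::summarise(dplyr::group_by(ev, age_month),
                               m = sum(deaths) / (sum(exposure) / 12))
    summary_rates(life_table(m_to_q(pooled$m)))$u5mr
  }
  expect_lt(u5(rec1), u5(rec0))
})

test_that("sampling weights are dispersed around one and default to one", {
  surf <- const_q_surface(0.01, 1993:2017)
  rec <- simulate_birth_histories(surf, survey_design(n_women = 500), seed = 10)
  expect_true(all(rec$weight == 1))
  rec2 <- simulate_birth_histories(surf,
    survey_design(n_women = 2000, weight_dispersion = 0.3), seed = 10)
  expect_gt(sd(rec2$weight), 0.1)
  expect_lt(abs(mean(unique(rec2$weight)) - 1), 0.1)
})
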