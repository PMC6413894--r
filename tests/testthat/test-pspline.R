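test_that("the B-spline basis is a partition of unity with the stated penalty", {
  b <- build_basis(0:59, degree = 3, knot_spacing = 2, penalty_order = 2)
  expect_equal(rowSums(b$B), rep(1, 60), tolerance = 1e-12)
  expect_equal(dim(b$D), c(b$nb - 2L, b$nb))
  # order-2 differences annihilate linear coefficient sequences
  expect_equal(max(abs(b$D %*% (1:b$nb))), 0)
  expect_error(build_basis(0:3, degree = 3, penalty_order = 2), "at least")
})

test_that("a degree-0 basis with one interval per point is identity-like", {
  b <- build_basis(0:9, degree = 0, knot_spacing = 0.95, penalty_order = 1)
  expect_equal(b$nb, 10L)
  expect_true(all(rowSums(b$B) == 1))
  y <- rnorm(10)
  expect_equal(as.vector(b$D %*% y), diff(y))  # penalty = raw differences
})

test_that("the 2-D penalty vanishes on a constant coefficient sheet", {
  bx <- build_basis(0:19, knot_spacing = 2)
  by <- build_basis(0:9, knot_spacing = 2)
  P <- kronecker(diag(by$nb), crossprod(bx$D)) +
    kronecker(crossprod(by$D), diag(bx$nb))
  a_const <- rep(1, bx$nb * by$nb)
  expect_equal(max(abs(P %*% a_const)), 0)
})

test_that("a huge penalty collapses the fit to the Poisson straight line", {
  set.seed(31)
  x <- 0:59
  e <- rep(6000, 60)
  D <- rpois(60, e / 12 * exp(-3 - 0.02 * x))
  fit <- fit_pspline(list(D = D, E = e), lambda = 1e8)
  g <- glm(D ~ x + offset(log(e / 12)), family = poisson)
  line <- coef(g)[1] + coef(g)[2] * x
  expect_lt(max(abs(fit$fitted$log_m - line)), 1e-3)
})

test_that("a vanishing penalty with a rich basis interpolates the counts", {
  set.seed(32)
  e <- rep(3000, 40)
  D <- rpois(40, e / 12 * exp(-3 + 0.3 * sin((0:39) / 5)))
  fit <- fit_pspline(list(D = D, E = e), lambda = 1e-8, knot_spacing = 1)
  expect_lt(max(abs(exp(fit$fitted$log_m) * e / 12 - D)), 1e-6)
})

test_that("zero-exposure cells are interpolated, not fitted", {
  set.seed(33)
  e <- rep(5000, 60); e[25] <- 0
  mu <- exp(-3 - 0.03 * (0:59))
  D <- rpois(60, e / 12 * mu); D[25] <- 0
  fit <- fit_pspline(list(D = D, E = e), lambda = 10)
  # interpolated value close to the smooth trend through the neighbours
  expect_lt(abs(fit$fitted$log_m[25] - log(mu[25])), 0.2)
  expect_error(fit_pspline(list(D = D, E = rep(0, 60))), "exposure")
})

test_that("BIC-selected smoothing beats the raw rates against known truth", {
  set.seed(34)
  x <- 0:59
  logm_true <- -2.5 - 0.1 * x + 0.002 * x^2
  e <- rep(2000, 60)
  D <- rpois(60, e / 12 * exp(logm_true))
  fit <- fit_pspline(list(D = D, E = e), lambda_grid = 10^seq(-2, 6))
  raw <- log(pmax(D, 0.5) / (e / 12))
  rmse <- function(z) sqrt(mean((z - logm_true)^2))
  expect_lt(rmse(fit$fitted$log_m), rmse(raw))
})

test_that("lambda selection returns single-point grids, favors smooth truth, and is deterministic", {
  set.seed(35)
  e <- rep(4000, 60)
  D <- rpois(60, e / 12 * exp(-3 - 0.02 * (0:59)))  # exactly linear truth
  ev <- list(D = D, E = e)
  expect_equal(select_lambda(ev, lambda_grid = 7)$lambda, 7)
  grid <- 10^seq(-2, 6)
  sel <- select_lambda(ev, lambda_grid = grid)
  expect_gte(sel$lambda, grid[length(grid) - 1])  # at or near the grid maximum
  sel2 <- select_lambda(ev, lambda_grid = grid)
  expect_identical(sel$profile$bic, sel2$profile$bic)
})

test_that("deviance decreases with lambda and the effective dimension is bracketed", {
  set.seed(36)
  e <- rep(3000, 60)
  D <- rpois(60, e / 12 * exp(-3 + 0.3 * sin((0:59) / 8)))
  lams <- 10^seq(6, -2, by = -2)
  fits <- lapply(lams, function(l) fit_pspline(list(D = D, E = e), lambda = l))
  devs <- vapply(fits, function(f) f$deviance, numeric(1))
  expect_true(all(diff(devs) <= 1e-8))
  eds <- vapply(fits, function(f) f$ed, numeric(1))
  nb <- build_basis(0:59)$nb
  expect_true(all(eds >= 2 - 1e-6 & eds <= nb + 1e-6))  # null space to basis size
})

test_that("the 2-D smooth agrees with an independent tensor-spline oracle", {
  skip_if_not_installed("mgcv")
  surf <- make_true_surface(years = 2000:2014, k_sigma = 0.1, e_sigma = 0.1,
                            seed = 37)
  M <- surface_matrix(surf)
  E <- matrix(2000, 60, 15)
  set.seed(38)
  D <- matrix(rpois(900, M * E / 12), 60)
  fit <- fit_pspline(list(D = D, E = E), lambda = NULL,
                     lambda_grid = 10^seq(0, 4, by = 2))
  dat <- data.frame(y = as.vector(D), x = rep(0:59, 15),
                    t = rep(1:15, each = 60), off = log(as.vector(E) / 12))
  g <- mgcv::gam(y ~ te(x, t, bs = "ps", k = c(12, 6)) + offset(off),
                 family = poisson, data = dat, method = "REML")
  # both smooths should sit close to the same underlying surface
  expect_lt(sqrt(mean((fit$fitted$log_m - (predict(g) - dat$off))^2)), 0.15)
})
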