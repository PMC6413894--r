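#' Equally spaced B-spline basis with a difference penalty
#'
#' Builds the regression basis for P-spline smoothing: equally spaced
#' B-splines of the given degree evaluated at the data positions, plus the
#' difference operator of the given order acting on the basis coefficients.
#' Interior rows of the basis sum to 1 (partition of unity).
#'
#' @param x Positions at which to evaluate the basis (e.g. age months).
#' @param degree B-spline degree (default 3, cubic).
#' @param knot_spacing Distance between adjacent knots on the scale of `x`
#'   (default 2).
#' @param penalty_order Order of the difference penalty (default 2, so the
#'   penalty null space contains straight lines in the coefficients).
#' @return A list with `B` (length(x) x nb basis matrix), `D` (difference
#'   operator, (nb - order) x nb), `knots`, `nb`, `degree`, `penalty_order`.
#' @examples
#' b <- build_basis(0:59)
#' range(rowSums(b$B))  # 1 1
#' @export
build_basis <- function(x, degree = 3, knot_spacing = 2, penalty_order = 2) {
  if (degree < 1 && degree != 0) abort("degree must be a nonnegative integer")
  if (penalty_order < 1) abort("penalty_order must be >= 1")
  ux <- sort(unique(x))
  if (length(ux) < penalty_order + degree + 1) {
    abort(sprintf("need at least %d distinct positions for degree %d, penalty order %d",
                  penalty_order + degree + 1, degree, penalty_order))
  }
  xl <- min(ux); xr <- max(ux)
  ndx <- max(1L, as.integer(ceiling((xr - xl) / knot_spacing)))
  dx <- (xr - xl) / ndx
  knots <- seq(xl - degree * dx, xr + degree * dx, by = dx)
  B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
  nb <- ncol(B)
  D <- diff(diag(nb), differences = penalty_order)
  list(B = B, D = D, knots = knots, nb = nb,
       degree = degree, penalty_order = penalty_order)
}

# assemble death/exposure matrices (age x year) from a long events tibble
events_matrices <- function(events) {
  if (is.list(events) && !is.data.frame(events) &&
      all(c("D", "E") %in% names(events))) {
    return(list(D = as.matrix(events$D), E = as.matrix(events$E),
                ages = seq_len(nrow(as.matrix(events$D))) - 1L,
                years = seq_len(ncol(as.matrix(events$D)))))
  }
  stopifnot(all(c("age_month", "year", "deaths", "exposure") %in% names(events)))
  Dm <- surface_matrix(events, "deaths")
  Em <- surface_matrix(events, "exposure")
  Dm[is.na(Dm)] <- 0
  Em[is.na(Em)] <- 0
  list(D = Dm, E = Em, ages = 0:59, years = as.integer(colnames(Dm)))
}

# penalized Poisson IRWLS for a fixed lambda; offset is log(E/12) so the
# fitted hazard is annualized; zero-exposure cells carry zero weight
pirls <- function(y, e, B, P, tol = 1e-8, maxit = 200L) {
  obs <- e > 0
  off <- ifelse(obs, log(e / 12), 0)
  eta <- ifelse(obs, log((y + 0.5) / (e / 12 + 0.5)), 0)
  alpha <- rep(0, ncol(B))
  # warm start: weighted LS of the initial eta on B
  w0 <- ifelse(obs, 1, 0)
  M0 <- crossprod(B * w0, B) + P + diag(1e-10, ncol(B))
  alpha <- solve(M0, crossprod(B * w0, eta))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(B %*% alpha)
    mu <- ifelse(obs, exp(off + eta), 0)
    w <- ifelse(obs, mu, 0)
    z <- ifelse(obs, eta + (y - mu) / pmax(mu, 1e-300), 0)
    M <- crossprod(B * w, B) + P
    alpha_new <- tryCatch(solve(M, crossprod(B * w, z)),
                          error = function(err) solve(M + diag(1e-10, ncol(B)),
                                                      crossprod(B * w, z)))
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (is.finite(delta) && delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(B %*% alpha)
  mu <- ifelse(obs, exp(off + eta), 0)
  w <- ifelse(obs, mu, 0)
  BtWB <- crossprod(B * w, B)
  H <- tryCatch(solve(BtWB + P, BtWB),
                error = function(err) solve(BtWB + P + diag(1e-10, ncol(B)), BtWB))
  ed <- sum(diag(H))
  dev_terms <- ifelse(obs & y > 0, y * log(y / pmax(mu, 1e-300)), 0) -
    ifelse(obs, y - mu, 0)
  dev <- 2 * sum(dev_terms)
  n_eff <- sum(obs)
  list(alpha = alpha, eta = eta, mu = mu, ed = ed, deviance = dev,
       bic = dev + log(n_eff) * ed, n_eff = n_eff,
       converged = converged, iter = it)
}

#' Smooth a mortality surface by penalized Poisson P-splines
#'
#' Fits death counts `D` with exposure offset `log(E/12)` (so the fitted
#' scale is the annualized hazard) by a Poisson GLM on an equally spaced
#' B-spline basis, with a difference penalty on the basis coefficients,
#' estimated by iteratively reweighted least squares. With a single year of
#' data the smooth is one-dimensional in age; otherwise the basis is the
#' Kronecker product of the age and year bases and the penalty the Kronecker
#' sum of the two one-dimensional difference penalties. Cells with zero
#' exposure carry zero weight and are interpolated by the smooth. The grids
#' here are small (60 ages by at most a few decades), so dense linear
#' algebra is used throughout.
#'
#' @param events A `u5_events` tibble (see [tabulate_events()]) or a list
#'   `list(D = , E = )` of age-by-year matrices. Non-integer "expected"
#'   death counts are accepted (used when smoothing calibrated rates).
#' @param lambda Smoothing parameter: a single value (1-D), a length-2
#'   vector `c(age, year)` (2-D), or `NULL` to select by BIC over
#'   `lambda_grid` (see [select_lambda()]).
#' @param degree,penalty_order Passed to [build_basis()].
#' @param knot_spacing Knot spacing per dimension: one knot per 2 age months
#'   and per 2 years by default; recycled to length 2 for 2-D fits.
#' @param lambda_grid Candidate values when `lambda` is `NULL`.
#' @param tol,maxit IRWLS convergence tolerance on `max |delta alpha|` and
#'   iteration cap; non-convergence is flagged, not an error.
#' @return An object of class `u5_pspline`: a list with `fitted` (tibble
#'   `age_month`, `year`, `log_m`, `m`), `alpha`, `lambda`, `ed` (effective
#'   dimension), `deviance`, `bic`, `converged`, `iter`.
#' @export
fit_pspline <- function(events, lambda = NULL, degree = 3, knot_spacing = 2,
                        penalty_order = 2, lambda_grid = 10^seq(-2, 6),
                        tol = 1e-8, maxit = 200L) {
  em <- events_matrices(events)
  if (all(em$E == 0)) abort("all-zero exposure: nothing to smooth")
  two_d <- ncol(em$D) > 1L
  if (is.null(lambda)) {
    lambda <- select_lambda(events, degree = degree, knot_spacing = knot_spacing,
                            penalty_order = penalty_order,
                            lambda_grid = lambda_grid,
                            tol = tol, maxit = maxit)$lambda
  }
  ks <- rep(knot_spacing, length.out = 2)
  bx <- build_basis(em$ages, degree, ks[1], penalty_order)
  if (two_d) {
    lambda <- rep(lambda, length.out = 2)
    by <- build_basis(em$years, degree, ks[2], penalty_order)
    B <- kronecker(by$B, bx$B)
    Px <- crossprod(bx$D)
    Py <- crossprod(by$D)
    P <- lambda[1] * kronecker(diag(by$nb), Px) +
      lambda[2] * kronecker(Py, diag(bx$nb))
    y <- as.vector(em$D); e <- as.vector(em$E)
  } else {
    lambda <- lambda[1]
    B <- bx$B
    P <- lambda * crossprod(bx$D)
    y <- em$D[, 1]; e <- em$E[, 1]
  }
  fit <- pirls(y, e, B, P, tol = tol, maxit = maxit)
  if (!fit$converged) {
    warn(sprintf("P-spline IRWLS did not converge in %d iterations", fit$iter))
  }
  fitted <- tibble(
    age_month = rep(em$ages, times = ncol(em$D)),
    year = rep(em$years, each = nrow(em$D)),
    log_m = fit$eta,
    m = exp(fit$eta)
  )
  structure(list(fitted = fitted, alpha = fit$alpha, lambda = lambda,
                 ed = fit$ed, deviance = fit$deviance, bic = fit$bic,
                 n_eff = fit$n_eff, converged = fit$converged, iter = fit$iter,
                 degree = degree, penalty_order = penalty_order,
                 knot_spacing = ks, two_d = two_d),
            class = "u5_pspline")
}

#' Select P-spline smoothing parameters by BIC
#'
#' Grid search minimizing `BIC = deviance + log(n_effective) * effective
#' dimension`; ties are broken toward larger (smoother) lambda. For 2-D
#' surfaces the grid is crossed over the two dimensions.
#'
#' @inheritParams fit_pspline
#' @return A list with `lambda` (the chosen value or pair) and `profile`
#'   (tibble of the grid with BIC, deviance, effective dimension).
#' @export
select_lambda <- function(events, degree = 3, knot_spacing = 2,
                          penalty_order = 2, lambda_grid = 10^seq(-2, 6),
                          tol = 1e-8, maxit = 200L) {
  if (length(lambda_grid) == 0) abort("lambda_grid must be nonempty")
  em <- events_matrices(events)
  two_d <- ncol(em$D) > 1L
  grid <- if (two_d) {
    tidyr::expand_grid(lambda_age = sort(lambda_grid),
                       lambda_year = sort(lambda_grid))
  } else {
    tibble(lambda_age = sort(lambda_grid))
  }
  prof <- purrr::pmap_dfr(grid, function(lambda_age, lambda_year = NULL) {
    lam <- if (two_d) c(lambda_age, lambda_year) else lambda_age
    f <- fit_pspline(events, lambda = lam, degree = degree,
                     knot_spacing = knot_spacing,
                     penalty_order = penalty_order, tol = tol, maxit = maxit)
    tibble(lambda_age = lambda_age,
           lambda_year = if (two_d) lambda_year else NA_real_,
           bic = f$bic, deviance = f$deviance, ed = f$ed)
  })
  # iterate ascending; <= prefers the larger lambda among ties
  best <- 1L
  for (i in seq_len(nrow(prof))) {
    if (prof$bic[i] <= prof$bic[best] + 1e-9) best <- i
  }
  lambda <- if (two_d) c(prof$lambda_age[best], prof$lambda_year[best]) else
    prof$lambda_age[best]
  list(lambda = lambda, profile = prof)
}

#' @export
print.u5_pspline <- function(x, ...) {
  cat(sprintf("P-spline Poisson smooth (%s), lambda = %s\n",
              if (x$two_d) "age x year" else "age",
              paste(signif(x$lambda, 3), collapse = " x ")))
  cat(sprintf("  effective dimension %.1f, deviance %.1f, BIC %.1f, %s in %d it.\n",
              x$ed, x$deviance, x$bic,
              if (x$converged) "converged" else "NOT converged", x$iter))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.u5_pspline <- function(x, ...) x$fitted

#' @exportS3Method generics::glance
glance.u5_pspline <- function(x, ...) {
  tibble(ed = x$ed, deviance = x$deviance, bic = x$bic, n_eff = x$n_eff,
         lambda_age = x$lambda[1],
         lambda_year = if (x$two_d) x$lambda[2] else NA_real_,
         converged = x$converged, iter = x$iter)
}

#' @exportS3Method ggplot2::autoplot
autoplot.u5_pspline <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
    ggplot2::aes(x = .data$age_month, y = .data$m,
                 group = .data$year, colour = .data$year)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (months)", y = "Smoothed annual death rate",
                  colour = "Year") +
    ggplot2::theme_minimal()
}
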