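# shared fixtures, all built in code

# surface with a constant monthly death probability q at every age and year
const_q_surface <- function(q, years) {
  tibble::tibble(
    age_month = rep(0:59, times = length(years)),
    year = rep(years, each = 60L),
    m = q_to_m(q)
  )
}

# noise-free "infinite population" events: expected deaths at the surface's
# rates under constant exposure (person-months per cell)
expected_events <- function(surface, exposure = 1e5) {
  M <- surface_matrix(surface)
  E <- matrix(exposure, nrow = nrow(M), ncol = ncol(M))
  list(D = M * E / 12, E = E, years = as.integer(colnames(M)))
}

# exact rank-1 log-mortality matrix from chosen normalized (a, b, k)
rank1_logm <- function(a, b, k, years) {
  M <- outer(a, rep(1, length(k))) + outer(b, k)
  colnames(M) <- years
  M
}

quiet_pipeline <- function(...) {
  suppressWarnings(suppressMessages(run_pipeline(...)))
}
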