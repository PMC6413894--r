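#' Century-month code (CMC) date helpers
#'
#' The DHS century-month code counts calendar months since January 1900:
#' `CMC = 12 * (year - 1900) + month`, so January 1900 is CMC 1. All age
#' arithmetic in this package is done in completed months on this scale.
#'
#' @param year Calendar year (integer vector).
#' @param month Calendar month, 1-12 (integer vector, recycled).
#' @param cmc Century-month code (integer vector).
#'
#' @return `cmc()` returns the century-month code; `cmc_year()` and
#'   `cmc_month()` return the calendar year and month containing a CMC.
#' @examples
#' cmc(2000, 1)        # 1201
#' cmc_year(1201)      # 2000
#' cmc_month(1201)     # 1
#' @export
cmc <- function(year, month = 1L) {
  stopifnot(all(month >= 1), all(month <= 12))
  as.integer(12L * (as.integer(year) - 1900L) + as.integer(month))
}

#' @rdname cmc
#' @export
cmc_year <- function(cmc) {
  1900L + (as.integer(cmc) - 1L) %/% 12L
}

#' @rdname cmc
#' @export
cmc_month <- function(cmc) {
  1L + (as.integer(cmc) - 1L) %% 12L
}

# internal: check a scalar numeric field is finite, naming the field
check_finite <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("field `%s` must be finite numeric", field))
  }
  invisible(x)
}
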