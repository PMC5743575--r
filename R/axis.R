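#' Wavenumber axis of an FTIR measurement
#'
#' Builds the descending, uniformly spaced wavenumber grid on which spectra are
#' sampled. The default covers the full mid-infrared range recorded by a
#' high-throughput transmission instrument: 4,000 down to 500 cm^-1 at a
#' digital spacing of 0.964 cm^-1 (3,631 points).
#'
#' @param start First (highest) wavenumber in cm^-1.
#' @param end Lower bound in cm^-1; the axis stops at the last grid point
#'   `>= end`.
#' @param spacing Digital spacing between consecutive points, in cm^-1.
#'
#' @return A numeric vector of strictly decreasing, uniformly spaced
#'   wavenumbers.
#' @examples
#' wn <- wavenumber_axis()
#' length(wn)
#' head(wn)
#' @export
wavenumber_axis <- function(start = 4000, end = 500, spacing = 0.964) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(spacing))
  if (spacing <= 0) abort("`spacing` must be positive.")
  if (start <= end) abort("`start` must exceed `end` for a descending axis.")
  n <- floor((start - end) / spacing) + 1L
  start - spacing * (seq_len(n) - 1)
}

# Validate a user-supplied axis: strictly monotone, uniform spacing.
check_axis <- function(wn, tol = 1e-9) {
  if (length(wn) < 2L) abort("Wavenumber axis needs at least two points.")
  d <- diff(wn)
  if (!(all(d < 0) || all(d > 0))) {
    abort("Wavenumber axis must be strictly monotone.")
  }
  if (max(abs(d - d[1])) > tol * max(1, abs(d[1]))) {
    abort("Wavenumber axis must be uniformly spaced.")
  }
  invisible(wn)
}

# Axis rescaled to [-1, 1]; used for EMSC / synthetic baseline polynomials.
axis_unit_scale <- function(wn) {
  r <- range(wn)
  if (r[1] == r[2]) abort("Degenerate wavenumber axis.")
  2 * (wn - r[1]) / (r[2] - r[1]) - 1
}
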