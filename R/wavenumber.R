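#' Uniform mid-infrared wavenumber grid
#'
#' Builds the ordered wavenumber sampling shared by all spectra in a scan.
#' The number of points follows the instrument's scan convention
#' `floor((stop - start) / step)`, so a 950--1240 cm^-1 sweep sampled at
#' 1.38 cm^-1 per point yields 210 points and the last point falls short
#' of `stop`.
#'
#' @param start first wavenumber (cm^-1).
#' @param stop end of the tuning range (cm^-1, exclusive under the floor
#'   convention unless it coincides with a sample).
#' @param step sampling density (cm^-1 per data point).
#' @return An object of class `wn_grid`: list with `start`, `stop`, `step`
#'   and the numeric vector `points`.
#' @examples
#' g <- make_wavenumber_grid(950, 1240, 1.38)
#' length(g$points)  # 210
#' @export
make_wavenumber_grid <- function(start, stop, step) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step) ||
      length(start) != 1L || length(stop) != 1L || length(step) != 1L) {
    stop("start, stop and step must be numeric scalars")
  }
  if (step <= 0) {
    stop("wavenumber step must be positive (got ", step, ")")
  }
  if (stop <= start) {
    stop("empty tuning range: stop (", stop, ") must exceed start (", start, ")")
  }
  # guard against floating-point shortfall when the range is an exact
  # multiple of the step
  n <- floor((stop - start) / step + sqrt(.Machine$double.eps))
  if (n < 1) {
    stop("tuning range shorter than one step: no sample points")
  }
  points <- start + (seq_len(n) - 1) * step
  structure(list(start = start, stop = stop, step = step, points = points),
            class = "wn_grid")
}

#' @export
length.wn_grid <- function(x) length(x$points)

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %g to %g cm^-1, step %g cm^-1, %d points\n",
              x$start, x$stop, x$step, length(x$points)))
  invisible(x)
}

#' Index of the grid point nearest a target wavenumber
#'
#' @param grid a `wn_grid`.
#' @param wavenumber target (cm^-1), vectorized.
#' @return integer indices into `grid$points`.
#' @export
nearest_grid_index <- function(grid, wavenumber) {
  stopifnot(inherits(grid, "wn_grid"))
  vapply(wavenumber, function(w) which.min(abs(grid$points - w)), integer(1))
}

same_grid <- function(a, b) {
  length(a$points) == length(b$points) &&
    max(abs(a$points - b$points)) < 1e-9
}
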