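#' @title Raster-scan and wavenumber-scan forward model
#' @description Internal helper: sample a ground-truth field through the
#'   Gaussian beam at given pixel centers. The kernel is discretized on the
#'   field's own grid, clipped at the field boundary and renormalized per
#'   pixel, so a spatially uniform field scans to an exactly uniform image.
#' @noRd
convolve_sample <- function(field, res, kernel, px, py) {
  nr <- nrow(field); nc <- ncol(field)
  r <- (nrow(kernel) - 1L) %/% 2L
  out <- matrix(NA_real_, length(py), length(px))
  jx <- pmin(pmax(floor(px / res) + 1L, 1L), nc)
  jy <- pmin(pmax(floor(py / res) + 1L, 1L), nr)
  for (iy in seq_along(py)) {
    y0 <- jy[iy] - r; y1 <- jy[iy] + r
    ky0 <- max(1L, 1L + (1L - y0)); ky1 <- (2L * r + 1L) - max(0L, y1 - nr)
    fy0 <- max(1L, y0); fy1 <- min(nr, y1)
    for (ix in seq_along(px)) {
      x0 <- jx[ix] - r; x1 <- jx[ix] + r
      kx0 <- max(1L, 1L + (1L - x0)); kx1 <- (2L * r + 1L) - max(0L, x1 - nc)
      fx0 <- max(1L, x0); fx1 <- min(nc, x1)
      k <- kernel[ky0:ky1, kx0:kx1, drop = FALSE]
      out[iy, ix] <- sum(k * field[fy0:fy1, fx0:fx1]) / sum(k)
    }
  }
  out
}

# unit absorption of an analyte at arbitrary wavenumbers (band-sum form,
# shared with component_spectrum); band_scale multiplies the band heights
# and band_shift displaces the centers (secretion composition fluctuation)
analyte_absorption <- function(analyte, wavenumber, band_scale = NULL,
                               band_shift = NULL) {
  bands <- default_bands(analyte)
  if (is.null(bands)) stop("unknown analyte '", analyte, "'")
  h <- bands$height
  ctr <- bands$center
  if (!is.null(band_scale)) h <- h * band_scale
  if (!is.null(band_shift)) ctr <- ctr + band_shift
  v <- numeric(length(wavenumber))
  for (i in seq_len(nrow(bands))) {
    v <- v + h[i] *
      exp(-(wavenumber - ctr[i])^2 / (2 * bands$width[i]^2))
  }
  v
}

#' Raster-scan photoacoustic image
#'
#' Simulates a 2-D position scan at a fixed wavenumber: at every pixel the
#' signal is the cell resonance gain times the pulse energy times the
#' beam-weighted local absorption, plus additive Gaussian noise whose sd is
#' reduced by the square root of the number of laser pulses averaged per
#' dwell (one lock-in time constant).
#'
#' @param map a [generate_skin_map()] skin map.
#' @param t minutes since hand washing.
#' @param wavenumber scan wavenumber (cm^-1); defaults to the configured
#'   imaging wavenumber (1040 cm^-1).
#' @param config an [instrument_config()].
#' @param origin_um scan origin offset (um); pixel centers sit at
#'   `origin + step * (k + 1/2)`.
#' @param noise logical; disable to obtain the noiseless forward model.
#' @param seed optional RNG seed.
#' @return a `pa_image`: list with `values` (matrix `[iy, ix]`),
#'   `pixel_pitch`, `origin`, `wavenumber`, `time`.
#' @export
raster_scan <- function(map, t, wavenumber = config$imaging_wavenumber,
                        config = instrument_config(), origin_um = c(0, 0),
                        noise = TRUE, seed = NULL) {
  stopifnot(inherits(map, "skin_map"), inherits(config, "instrument_config"))
  if (!is.null(seed)) set.seed(seed)
  fov <- config$n_pixels * config$step
  if (any(origin_um < 0) || any(origin_um + fov > map$extent + 1e-9)) {
    stop("map extent (", map$extent, " um) does not cover the ", fov,
         " um scan field at the requested origin")
  }
  e_nj <- pulse_energy(config, wavenumber)  # errors off-domain
  gain <- cell_gain(config$rep_rate, config)
  jit <- draw_secretion_jitter(map)
  fields <- skin_concentration_fields(map, t, jitter = jit$amp)
  kernel <- beam_kernel(config, map$resolution)
  px <- origin_um[1] + config$step * (seq_len(config$n_pixels) - 0.5)
  py <- origin_um[2] + config$step * (seq_len(config$n_pixels) - 0.5)
  vals <- matrix(0, config$n_pixels, config$n_pixels)
  for (analyte in names(fields)) {
    absn <- analyte_absorption(
      analyte, wavenumber,
      band_scale = if (analyte == "sodium_lactate") jit$band_scale,
      band_shift = if (analyte == "sodium_lactate") jit$band_shift)
    if (absn == 0) next
    vals <- vals + absn * convolve_sample(fields[[analyte]], map$resolution,
                                          kernel, px, py)
  }
  vals <- gain * e_nj * vals
  if (noise && config$noise_sigma > 0) {
    ppt <- laser_accounting(config)$pulses_per_tc
    vals <- vals + stats::rnorm(length(vals),
                                0, config$noise_sigma / sqrt(ppt))
  }
  structure(list(values = vals, pixel_pitch = config$step,
                 origin = origin_um, wavenumber = wavenumber, time = t),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("<pa_image> %d x %d px at %g um pitch, %g cm^-1, t = %g min\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch, x$wavenumber,
              x$time))
  invisible(x)
}

#' Pixel center coordinates of a raster image
#'
#' @param image a `pa_image`.
#' @return list with vectors `x`, `y` (um).
#' @export
pixel_centers <- function(image) {
  list(x = image$origin[1] + image$pixel_pitch *
         (seq_len(ncol(image$values)) - 0.5),
       y = image$origin[2] + image$pixel_pitch *
         (seq_len(nrow(image$values)) - 0.5))
}

#' Acquire a photoacoustic wavenumber-scan spectrum at one position
#'
#' Tunes the laser across the wavenumber grid with the beam parked at one
#' skin position. The noiseless signal at each wavenumber is
#' `gain * pulse_energy(wn) * sum_c w_c * S_c(wn)` where `w_c` is the
#' beam-weighted concentration of analyte `c`; additive noise has sd
#' `noise_sigma / sqrt(pulses_per_tc * n_repeats)` (lock-in averaging plus
#' repeat-scan averaging).
#'
#' @param map a `skin_map`.
#' @param position_um `c(x, y)` probing position (um), inside the map.
#' @param t minutes since hand washing.
#' @param grid a `wn_grid`; every grid point must lie on the pulse-energy
#'   curve domain.
#' @param config an [instrument_config()].
#' @param noise logical; disable for the noiseless forward model.
#' @param seed optional RNG seed.
#' @return a `pa_spectrum`: list with `grid`, `values`, `position`,
#'   `time`, `normalized = FALSE`.
#' @export
acquire_spectrum <- function(map, position_um, t,
                             grid = make_wavenumber_grid(950, 1240, 1.38),
                             config = instrument_config(), noise = TRUE,
                             seed = NULL) {
  stopifnot(inherits(map, "skin_map"), length(position_um) == 2)
  if (!is.null(seed)) set.seed(seed)
  if (any(position_um < 0) || any(position_um > map$extent)) {
    stop("probing position (", position_um[1], ", ", position_um[2],
         ") um lies outside the ", map$extent, " um skin map")
  }
  e_nj <- pulse_energy(config, grid$points)
  gain <- cell_gain(config$rep_rate, config)
  jit <- draw_secretion_jitter(map)
  fields <- skin_concentration_fields(map, t, jitter = jit$amp)
  kernel <- beam_kernel(config, map$resolution)
  w <- vapply(fields, function(f) {
    convolve_sample(f, map$resolution, kernel,
                    position_um[1], position_um[2])[1, 1]
  }, numeric(1))
  vals <- numeric(length(grid$points))
  for (analyte in names(w)) {
    vals <- vals + w[[analyte]] * analyte_absorption(
      analyte, grid$points,
      band_scale = if (analyte == "sodium_lactate") jit$band_scale,
      band_shift = if (analyte == "sodium_lactate") jit$band_shift)
  }
  vals <- gain * e_nj * vals
  if (noise && config$noise_sigma > 0) {
    ppt <- laser_accounting(config)$pulses_per_tc
    vals <- vals + stats::rnorm(length(vals), 0,
                                config$noise_sigma /
                                  sqrt(ppt * config$n_repeats))
  }
  structure(list(grid = grid, values = vals, position = position_um,
                 time = t, normalized = FALSE), class = "pa_spectrum")
}

#' @export
print.pa_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pa_spectrum> %d points at (%g, %g) um, t = %g min%s\n",
    length(x$values), x$position[1], x$position[2], x$time,
    if (x$normalized) ", pulse-energy normalized" else ""))
  invisible(x)
}

#' Normalize a spectrum by the pulse-energy tuning curve
#'
#' Divides the raw signal pointwise by the laser pulse energy at each
#' wavenumber, removing the tuning-curve envelope. Normalizing an
#' already-normalized spectrum is rejected.
#'
#' @param s a `pa_spectrum`.
#' @param config an [instrument_config()].
#' @return the normalized `pa_spectrum` (flag set).
#' @export
normalize_by_pulse_energy <- function(s, config = instrument_config()) {
  stopifnot(inherits(s, "pa_spectrum"))
  if (isTRUE(s$normalized)) {
    stop("spectrum is already pulse-energy normalized")
  }
  e <- pulse_energy(config, s$grid$points)
  if (any(e <= 0)) {
    stop("pulse-energy curve must be strictly positive on the grid")
  }
  s$values <- s$values / e
  s$normalized <- TRUE
  s
}

#' Modulation contrast of a bar resolution target
#'
#' Simulates a noiseless scan across an equal line/space bar target
#' (absorbing lines on a non-absorbing background, the SU-8 resolution
#' fixture analog) with the Gaussian beam, and reports the modulation
#' contrast `(max - min) / (max + min)` of the profile over the central
#' periods.
#'
#' @param line_width_um bar width (um); the period is twice this.
#' @param config an [instrument_config()].
#' @return contrast in `[0, 1]`.
#' @export
resolution_contrast <- function(line_width_um, config = instrument_config()) {
  stopifnot(line_width_um > 0)
  sigma <- config$beam_diameter / 4
  res <- max(0.25, min(line_width_um / 20, sigma / 10, 2))
  period <- 2 * line_width_um
  margin <- 3 * sigma + period
  width <- 6 * period + 2 * margin
  x <- seq(res / 2, width, by = res)
  target <- matrix(as.numeric((x %% period) < line_width_um), nrow = 1)
  kernel <- beam_kernel(config, res)
  profile <- convolve_sample(target, res, kernel, x, res / 2)[1, ]
  central <- x > margin & x < width - margin
  p <- profile[central]
  if (max(p) + min(p) == 0) return(0)
  (max(p) - min(p)) / (max(p) + min(p))
}

#' Smallest resolved line width of the bar-target simulation
#'
#' Scans bar targets over a range of line widths and reports the smallest
#' width whose modulation contrast meets the resolution criterion
#' (contrast >= 0.10), requiring every larger width in the scan to be
#' resolved as well.
#'
#' @param config an [instrument_config()].
#' @param widths_um candidate line widths (um).
#' @param threshold contrast criterion for "resolved".
#' @return list with `limit_um`, `widths_um`, `contrast`.
#' @export
resolution_limit <- function(config = instrument_config(),
                             widths_um = seq(10, 150, by = 2),
                             threshold = 0.10) {
  widths_um <- sort(widths_um)
  contrast <- vapply(widths_um, resolution_contrast, numeric(1),
                     config = config)
  resolved <- rev(cumprod(rev(contrast >= threshold))) > 0
  if (!any(resolved)) {
    stop("no candidate line width is resolved at contrast >= ", threshold)
  }
  list(limit_um = min(widths_um[resolved]), widths_um = widths_um,
       contrast = contrast)
}
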