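#' Scanning photoacoustic instrument configuration
#'
#' Parameters of the mid-infrared scanning photoacoustic setup: a pulsed
#' tunable quantum-cascade laser focused to a 90 um spot raster-scans the
#' skin in a 30 x 30 window at 44 um steps; the acoustic response is
#' amplified by the resonant cell (Q = 17 at 47.5 kHz) and detected with a
#' 30 ms lock-in time constant, so each dwell averages 1425 laser pulses;
#' wavenumber scans are additionally averaged over 16 repeats.
#'
#' @param beam_diameter_um Gaussian beam diameter (um), taken as the 1/e^2
#'   intensity diameter.
#' @param focal_distance_mm focal distance (mm), informational.
#' @param n_pixels raster pixels per axis.
#' @param step_um raster step (um); pixel centers sit at
#'   `step * (k + 1/2)` from the scan origin.
#' @param imaging_wavenumber wavenumber used for 2-D position scans
#'   (cm^-1).
#' @param rep_rate_hz laser repetition rate (Hz).
#' @param pulse_width_ns laser pulse width (ns).
#' @param lockin_tc_ms lock-in time constant (ms).
#' @param n_repeats wavenumber scans averaged per spectrum.
#' @param cell_f0_hz photoacoustic cell resonance frequency (Hz).
#' @param cell_q cell quality factor.
#' @param noise_sigma per-pulse signal noise sd (arbitrary units); lock-in
#'   and repeat averaging reduce it by `sqrt(pulses averaged)`.
#' @param pulse_energy_curve data.frame with columns `wavenumber_cm_1`,
#'   `energy_nJ`; defaults to [default_pulse_energy_curve()].
#' @return an `instrument_config` list.
#' @export
instrument_config <- function(beam_diameter_um = 90,
                              focal_distance_mm = 50.4,
                              n_pixels = 30,
                              step_um = 44,
                              imaging_wavenumber = 1040,
                              rep_rate_hz = 47500,
                              pulse_width_ns = 500,
                              lockin_tc_ms = 30,
                              n_repeats = 16,
                              cell_f0_hz = 47500,
                              cell_q = 17,
                              noise_sigma = 45,
                              pulse_energy_curve = default_pulse_energy_curve()) {
  vals <- c(beam_diameter_um, focal_distance_mm, n_pixels, step_um,
            imaging_wavenumber, rep_rate_hz, pulse_width_ns, lockin_tc_ms,
            n_repeats, cell_f0_hz, cell_q)
  if (any(vals <= 0)) stop("all physical instrument quantities must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  stopifnot(is.data.frame(pulse_energy_curve),
            all(c("wavenumber_cm_1", "energy_nJ") %in%
                  names(pulse_energy_curve)))
  structure(list(
    beam_diameter = beam_diameter_um, focal_distance = focal_distance_mm,
    n_pixels = as.integer(n_pixels), step = step_um,
    imaging_wavenumber = imaging_wavenumber,
    rep_rate = rep_rate_hz, pulse_width = pulse_width_ns,
    lockin_tc = lockin_tc_ms, n_repeats = as.integer(n_repeats),
    cell_f0 = cell_f0_hz, cell_q = cell_q, noise_sigma = noise_sigma,
    pulse_energy_curve = pulse_energy_curve
  ), class = "instrument_config")
}

#' Default laser pulse-energy curve
#'
#' Smooth synthetic tuning curve of the quantum-cascade laser: a Gaussian
#' in wavenumber peaking at 1000 cm^-1 with the 44.2 nJ maximum
#' single-pulse energy.
#'
#' @param from,to,by tabulation range and spacing (cm^-1).
#' @param peak_energy_nJ maximum single-pulse energy (nJ).
#' @param center_cm_1,width_cm_1 Gaussian center and sigma (cm^-1).
#' @return data.frame with `wavenumber_cm_1`, `energy_nJ`.
#' @export
default_pulse_energy_curve <- function(from = 900, to = 1250, by = 1,
                                       peak_energy_nJ = 44.2,
                                       center_cm_1 = 1000,
                                       width_cm_1 = 150) {
  wn <- seq(from, to, by = by)
  data.frame(wavenumber_cm_1 = wn,
             energy_nJ = peak_energy_nJ *
               exp(-(wn - center_cm_1)^2 / (2 * width_cm_1^2)))
}

#' Pulse energy at given wavenumbers
#'
#' Linear interpolation of the configured pulse-energy curve; wavenumbers
#' outside the tabulated domain are rejected.
#'
#' @param config an [instrument_config()].
#' @param wavenumber cm^-1, vectorized.
#' @return energies (nJ).
#' @export
pulse_energy <- function(config, wavenumber) {
  crv <- config$pulse_energy_curve
  if (any(wavenumber < min(crv$wavenumber_cm_1) |
            wavenumber > max(crv$wavenumber_cm_1))) {
    stop("wavenumber outside the pulse-energy curve domain [",
         min(crv$wavenumber_cm_1), ", ", max(crv$wavenumber_cm_1), "] cm^-1")
  }
  stats::approx(crv$wavenumber_cm_1, crv$energy_nJ, xout = wavenumber)$y
}

#' Gaussian beam intensity kernel
#'
#' Rotationally symmetric Gaussian intensity profile with 1/e^2 diameter
#' equal to the configured beam diameter, discretized at the requested
#' pitch, truncated at three standard deviations and normalized to unit
#' sum. For a 1/e^2 radius `w = beam_diameter / 2` the intensity sd is
#' `w / 2`, giving an intensity FWHM of `beam_diameter * sqrt(ln 2 / 2)`
#' (about 53 um for the 90 um beam).
#'
#' @param config an [instrument_config()].
#' @param pixel_pitch_um sampling pitch of the kernel (um).
#' @return square numeric matrix summing to 1, with attribute `pitch`.
#' @export
beam_kernel <- function(config, pixel_pitch_um) {
  stopifnot(config$beam_diameter > 0, pixel_pitch_um > 0)
  if (pixel_pitch_um > config$beam_diameter) {
    warning("kernel undersampled: pitch ", pixel_pitch_um,
            " um exceeds the ", config$beam_diameter, " um beam diameter")
  }
  sigma <- config$beam_diameter / 4  # intensity sd for a 1/e^2 diameter
  r <- ceiling(3 * sigma / pixel_pitch_um)
  off <- (-r:r) * pixel_pitch_um
  d2 <- outer(off^2, off^2, "+")
  k <- exp(-d2 / (2 * sigma^2))
  k[sqrt(d2) > 3 * sigma + 1e-9] <- 0
  k <- k / sum(k)
  attr(k, "pitch") <- pixel_pitch_um
  attr(k, "sigma") <- sigma
  k
}

#' Photoacoustic cell resonance gain
#'
#' Lorentzian amplitude response of the resonant cell/microphone pair:
#' unit gain at the resonance `cell_f0` with half-power full width
#' `cell_f0 / cell_q` (about 2.8 kHz for Q = 17 at 47.5 kHz).
#'
#' @param f modulation frequency (Hz), vectorized.
#' @param config an [instrument_config()].
#' @return gain in `(0, 1]`.
#' @export
cell_gain <- function(f, config) {
  if (any(f <= 0)) stop("frequency must be positive")
  1 / (1 + (2 * config$cell_q * (f - config$cell_f0) / config$cell_f0)^2)
}

#' Laser pulse and power accounting
#'
#' Bookkeeping that links the lock-in time constant to the number of laser
#' pulses averaged per dwell and converts pulse energy to average and peak
#' power: 47.5 kHz x 30 ms = 1425 pulses; 44.2 nJ x 47.5 kHz = 2.1 mW
#' average; 44.2 nJ / 500 ns = 88.4 mW peak.
#'
#' @param config an [instrument_config()].
#' @param pulse_energy_nJ single-pulse energy used for the power figures;
#'   defaults to the maximum of the configured curve.
#' @return list with `pulses_per_tc`, `avg_power_mW`, `peak_power_mW`.
#' @export
laser_accounting <- function(config,
                             pulse_energy_nJ = max(config$pulse_energy_curve$energy_nJ)) {
  stopifnot(config$rep_rate > 0, config$lockin_tc > 0,
            config$pulse_width > 0, pulse_energy_nJ > 0)
  list(
    pulses_per_tc = round(config$rep_rate * config$lockin_tc / 1000),
    avg_power_mW = pulse_energy_nJ * 1e-9 * config$rep_rate * 1e3,
    peak_power_mW = pulse_energy_nJ / config$pulse_width * 1e3
  )
}
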