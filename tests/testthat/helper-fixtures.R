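# shared fixtures: small, fast variants of the study objects

# quiet instrument: no detector noise
quiet_config <- function(...) {
  instrument_config(noise_sigma = 0, ...)
}

# coarse deterministic map with no pores and no secretion fluctuation;
# uniform when flat = TRUE
toy_map <- function(extent = 440, res = 11, flat = FALSE, seed = 1, ...) {
  generate_skin_map(
    extent_um = extent, resolution_um = res,
    gland_density_cm2 = 0,
    baseline_b1 = if (flat) 0 else 0.5,
    secretion_noise_rel = 0, secretion_band_noise_rel = 0,
    secretion_band_shift_cm1 = 0,
    seed = seed, ...)
}

# wrap a plain matrix as a pa_image
as_image <- function(values, pitch = 44, wavenumber = 1040) {
  structure(list(values = values, pixel_pitch = pitch, origin = c(0, 0),
                 wavenumber = wavenumber, time = 0), class = "pa_image")
}

# wrap values on a grid as a pa_spectrum
as_spectrum <- function(values, grid, normalized = FALSE) {
  structure(list(grid = grid, values = values, position = c(0, 0),
                 time = 0, normalized = normalized), class = "pa_spectrum")
}

default_grid <- function() make_wavenumber_grid(950, 1240, 1.38)

# Moore-Penrose pseudoinverse via SVD (independent least-squares oracle)
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > max(s$d) * tol
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
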