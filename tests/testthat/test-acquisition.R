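# independent dense-convolution oracle: for each pixel, Gaussian intensity
# weights over every ground-truth cell (3-sigma circular support,
# renormalized), applied to each analyte field
oracle_raster <- function(map, t, wavenumber, config) {
  fields <- skin_concentration_fields(map, t)
  sigma <- config$beam_diameter / 4
  ctr <- map$centers
  px <- config$step * (seq_len(config$n_pixels) - 0.5)
  gain <- cell_gain(config$rep_rate, config)
  e <- pulse_energy(config, wavenumber)
  out <- matrix(0, config$n_pixels, config$n_pixels)
  snap <- function(p) ctr[floor(p / map$resolution) + 1]
  for (iy in seq_len(config$n_pixels)) for (ix in seq_len(config$n_pixels)) {
    cx <- snap(px[ix]); cy <- snap(px[iy])
    d2 <- outer((ctr - cy)^2, (ctr - cx)^2, "+")
    w <- exp(-d2 / (2 * sigma^2))
    w[sqrt(d2) > 3 * sigma + 1e-9] <- 0
    w <- w / sum(w)
    acc <- 0
    for (analyte in names(fields)) {
      acc <- acc + paglucose:::analyte_absorption(analyte, wavenumber) *
        sum(w * fields[[analyte]])
    }
    out[iy, ix] <- gain * e * acc
  }
  out
}

test_that("raster scan equals the dense convolution oracle on a toy map", {
  map <- toy_map(extent = 440, res = 11)
  map <- add_pore(map, 230, 180, s_max = 2)
  cfg <- quiet_config(n_pixels = 10, step_um = 44)
  img <- raster_scan(map, t = 60, config = cfg)
  expect_equal(img$values, oracle_raster(map, 60, cfg$imaging_wavenumber, cfg),
               tolerance = 1e-6)
})

test_that("a uniform skin map scans to a uniform image", {
  map <- toy_map(flat = TRUE)
  cfg <- quiet_config(n_pixels = 10, step_um = 44)
  img <- raster_scan(map, t = 0, config = cfg)
  expect_lt(diff(range(img$values)) / mean(img$values), 1e-9)
})

test_that("a saturated pore dominates the image at its own pixel", {
  map <- toy_map(extent = 440, res = 11, flat = TRUE)
  map <- add_pore(map, 220, 220, s_max = 2)
  cfg <- quiet_config(n_pixels = 10, step_um = 44)
  img <- raster_scan(map, t = 300, config = cfg)
  ctr <- pixel_centers(img)
  amx <- which(img$values == max(img$values), arr.ind = TRUE)
  expect_lte(abs(ctr$x[amx[1, 2]] - 220), cfg$step)
  expect_lte(abs(ctr$y[amx[1, 1]] - 220), cfg$step)
})

test_that("the 30 x 44 um window covers a 1.3 mm field of view", {
  cfg <- instrument_config()
  fov_mm <- cfg$n_pixels * cfg$step / 1000
  expect_equal(round(fov_mm, 1), 1.3)
})

test_that("scan geometry and wavenumber domain are validated", {
  map <- toy_map(extent = 440, res = 11)
  expect_error(raster_scan(map, 0, config = quiet_config()),
               "does not cover")
  expect_error(raster_scan(map, 0, wavenumber = 500,
                           config = quiet_config(n_pixels = 10)),
               "domain")
})

test_that("spectra vanish without absorbers and scale with pulse energy", {
  bare <- generate_skin_map(extent_um = 440, resolution_um = 11,
                            gland_density_cm2 = 0, baseline_b0 = 0,
                            baseline_b1 = 0, kappa_glucose = 0,
                            secretion_noise_rel = 0,
                            secretion_band_noise_rel = 0,
                            secretion_band_shift_cm1 = 0, seed = 1)
  g <- default_grid()
  s <- acquire_spectrum(bare, c(220, 220), 0, g, quiet_config())
  expect_equal(s$values, rep(0, length(g$points)))

  map <- toy_map(extent = 440, res = 11)
  cfg1 <- quiet_config()
  curve2 <- default_pulse_energy_curve()
  curve2$energy_nJ <- 2 * curve2$energy_nJ
  cfg2 <- quiet_config(pulse_energy_curve = curve2)
  s1 <- acquire_spectrum(map, c(220, 220), 10, g, cfg1)
  s2 <- acquire_spectrum(map, c(220, 220), 10, g, cfg2)
  expect_equal(s2$values, 2 * s1$values)

  expect_error(acquire_spectrum(map, c(500, 220), 0, g, cfg1), "outside")
})

test_that("noiseless forward model is linear in analyte concentrations", {
  g <- default_grid()
  cfg <- quiet_config()
  m1 <- toy_map(extent = 440, res = 11, flat = TRUE,
                kappa_glucose = 0)                        # baseline only
  m2 <- toy_map(extent = 440, res = 11, flat = TRUE,
                kappa_glucose = 0, baseline_b0 = 2)       # doubled baseline
  s1 <- acquire_spectrum(m1, c(220, 220), 0, g, cfg)$values
  s2 <- acquire_spectrum(m2, c(220, 220), 0, g, cfg)$values
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("acquisition noise tracks the closed-form averaging prediction", {
  map <- toy_map(extent = 440, res = 20)
  g <- make_wavenumber_grid(1000, 1100, 25)
  set.seed(11)
  for (n_rep in c(1, 4, 16)) {
    cfg <- instrument_config(n_repeats = n_rep)
    v <- replicate(3000,
                   acquire_spectrum(map, c(220, 220), 0, g, cfg)$values[1])
    predicted <- cfg$noise_sigma / sqrt(1425 * n_rep)
    expect_equal(stats::sd(v), predicted, tolerance = 0.05)
  }
})

test_that("pulse-energy normalization inverts the tuning curve once", {
  map <- toy_map(extent = 440, res = 11)
  g <- default_grid()
  cfg <- quiet_config()
  raw <- acquire_spectrum(map, c(220, 220), 0, g, cfg)
  norm <- normalize_by_pulse_energy(raw, cfg)
  expect_true(norm$normalized)
  expect_equal(norm$values, raw$values / pulse_energy(cfg, g$points))
  expect_error(normalize_by_pulse_energy(norm, cfg), "already")

  flat <- quiet_config(pulse_energy_curve = data.frame(
    wavenumber_cm_1 = c(900, 1250), energy_nJ = c(1, 1)))
  raw2 <- acquire_spectrum(map, c(220, 220), 0, g, flat)
  norm2 <- normalize_by_pulse_energy(raw2, flat)
  expect_equal(norm2$values, raw2$values)
})

test_that("bar-target contrast resolves the beam-limited line widths", {
  cfg <- instrument_config()
  expect_gt(resolution_contrast(900, cfg), 0.95)
  expect_gte(resolution_contrast(90, cfg), 0.10)
  expect_lt(resolution_contrast(9, cfg), 0.05)

  widths <- c(15, 25, 40, 60, 90, 140)
  ctr <- vapply(widths, resolution_contrast, numeric(1), config = cfg)
  expect_true(all(diff(ctr) >= 0))
})
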