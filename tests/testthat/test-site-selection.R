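test_that("blob segmentation finds constructed blobs and ignores flat images", {
  expect_equal(nrow(segment_blobs(as_image(matrix(5, 30, 30)))$summaries), 0)

  # one Gaussian blob with peak 10 MAD above the median of a noisy floor
  set.seed(3)
  v <- matrix(rnorm(900, 10, 1), 30, 30)
  madv <- stats::mad(v)
  add_blob <- function(v, r0, c0, peak) {
    for (i in 1:30) for (j in 1:30) {
      v[i, j] <- v[i, j] + peak * exp(-((i - r0)^2 + (j - c0)^2) / (2 * 1.5^2))
    }
    v
  }
  b1 <- segment_blobs(as_image(add_blob(v, 15, 18, 10 * madv)))
  expect_equal(nrow(b1$summaries), 1)
  expect_lt(abs(b1$summaries$centroid_row - 15), 1)
  expect_lt(abs(b1$summaries$centroid_col - 18), 1)

  # two blobs more than 3 beam diameters (> 6 px at 44 um) apart
  b2 <- segment_blobs(as_image(add_blob(add_blob(v, 8, 8, 10 * madv),
                                        24, 22, 12 * madv)))
  expect_equal(nrow(b2$summaries), 2)
})

test_that("blob labeling is 8-connected", {
  v <- matrix(0, 5, 5)
  v[cbind(c(1, 2, 4), c(1, 2, 5))] <- 100  # two diagonal pixels + one far
  b <- segment_blobs(as_image(v), min_area = 1)
  expect_equal(nrow(b$summaries), 2)  # diagonal pair merges
})

test_that("site selection returns the extreme pixels with fixed tie-breaks", {
  v <- matrix(10, 6, 6)
  v[2, 5] <- 20; v[4, 3] <- 1
  sel <- select_probe_sites(as_image(v))
  expect_equal(c(sel$bright_site$row, sel$bright_site$col), c(2, 5))
  expect_equal(c(sel$dark_site$row, sel$dark_site$col), c(4, 3))
  expect_false(sel$degenerate)

  flat <- select_probe_sites(as_image(matrix(7, 4, 4)))
  expect_true(flat$degenerate)
  expect_equal(c(flat$bright_site$row, flat$bright_site$col), c(1, 1))
  # distinct-pixel contract: dark site moves to the next row-major pixel
  expect_equal(c(flat$dark_site$row, flat$dark_site$col), c(1, 2))

  # selection is a pure function of the image
  expect_identical(select_probe_sites(as_image(v)), sel)
})

test_that("on ridge-and-pore maps the dark site sits on a valley floor", {
  for (s in c(2, 5, 9)) {
    map <- generate_skin_map(seed = s, resolution_um = 11,
                             secretion_noise_rel = 0,
                             secretion_band_noise_rel = 0,
                             secretion_band_shift_cm1 = 0)
    img <- raster_scan(map, t = 60, config = quiet_config())
    sel <- select_probe_sites(img)
    expect_lt(ridge_at(map, sel$dark_site$x_um, sel$dark_site$y_um), 0.2)
  }
})

test_that("detected blob centroids fall on true pore positions", {
  found <- 0
  for (s in c(2, 5, 9, 42)) {
    map <- generate_skin_map(seed = s, resolution_um = 11,
                             secretion_noise_rel = 0,
                             secretion_band_noise_rel = 0,
                             secretion_band_shift_cm1 = 0)
    img <- raster_scan(map, t = 90, config = quiet_config())
    b <- segment_blobs(img)
    for (k in seq_len(nrow(b$summaries))) {
      d <- sqrt((map$pores$x - b$summaries$centroid_x_um[k])^2 +
                  (map$pores$y - b$summaries$centroid_y_um[k])^2)
      expect_lt(min(d), 90)  # within one beam diameter
      found <- found + 1
    }
  }
  expect_gt(found, 0)
})

test_that("difference spectra isolate the secretion component", {
  g <- default_grid()
  lac <- component_spectrum("sodium_lactate", g)$values
  dark <- as_spectrum(0.5 * component_spectrum("skin_baseline", g)$values, g)
  bright <- as_spectrum(dark$values + 0.3 * lac, g)
  d <- difference_spectrum(bright, dark)
  expect_equal(d$values, 0.3 * lac)

  expect_equal(difference_spectrum(dark, dark)$values, rep(0, 210))
  expect_equal(difference_spectrum(dark, bright)$values, -d$values)

  other <- as_spectrum(rep(1, 105), make_wavenumber_grid(950, 1240, 2.76))
  expect_error(difference_spectrum(bright, other), "different wavenumber grids")
  norm <- dark; norm$normalized <- TRUE
  expect_error(difference_spectrum(bright, norm), "normalization state")
})

test_that("analyte matching identifies lactate and handles degenerate input", {
  g <- default_grid()
  lib <- default_spectral_library(g, c("glucose", "sodium_lactate",
                                       "skin_baseline"))
  d <- as_spectrum(lib$sodium_lactate$values, g)
  m <- match_analyte(d, lib)
  expect_equal(m$best, "sodium_lactate")
  expect_equal(unname(m$scores["sodium_lactate"]), 1)

  flat <- as_spectrum(rep(2, 210), g)
  m0 <- match_analyte(flat, lib)
  expect_true(is.na(m0$best))
  expect_true(all(is.na(m0$scores)))
})

test_that("secretion monitoring channels grow and saturate only where pores sit", {
  map <- toy_map(extent = 1320, res = 22)
  map <- add_pore(map, 660, 660, s_max = 2)
  cfg <- quiet_config()
  times <- seq(0, 90, by = 15)

  quiet_site <- monitor_secretion(map, c(110, 110), times, config = cfg)
  expect_lt(diff(range(quiet_site[[2]])), 1e-6 * max(1, max(quiet_site[[2]])))

  pore_site <- monitor_secretion(map, c(660, 660), times, config = cfg)
  for (ch in 2:3) {
    y <- pore_site[[ch]]
    expect_true(all(diff(y) > 0))          # strictly increasing
    expect_true(all(diff(diff(y)) < 0))    # concave (saturating)
  }
  sat <- monitor_secretion(map, c(660, 660), c(60, 240), config = cfg)
  expect_gte(sat[[2]][1], 0.98 * sat[[2]][2])  # saturated by one hour
  expect_error(monitor_secretion(map, c(660, 660), c(10, 5), config = cfg),
               "sorted")
})

test_that("bright-site signal grows with secretion amplitude, dark site does not", {
  g <- default_grid()
  cfg <- quiet_config()
  idx <- nearest_grid_index(g, c(1070, 1105, 1140))
  vals <- vapply(c(0.5, 1, 2, 4), function(sm) {
    map <- toy_map(extent = 440, res = 11)
    map <- add_pore(map, 231, 231, s_max = sm)
    s <- acquire_spectrum(map, c(231, 231), 60, g, cfg)
    sum(s$values[idx])
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  dark_vals <- vapply(c(0, 2), function(sm) {
    map <- toy_map(extent = 1320, res = 22)
    map <- add_pore(map, 660, 660, s_max = sm)
    acquire_spectrum(map, c(100, 100), 60, g, cfg)$values[idx[1]]
  }, numeric(1))
  expect_equal(dark_vals[1], dark_vals[2], tolerance = 1e-6)
})
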