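test_that("pore placement respects density, ridge tops and determinism", {
  m0 <- generate_skin_map(gland_density_cm2 = 0, resolution_um = 20, seed = 1)
  expect_equal(nrow(m0$pores), 0L)

  a <- generate_skin_map(seed = 7, resolution_um = 20)
  b <- generate_skin_map(seed = 7, resolution_um = 20)
  expect_identical(a$ridge_field, b$ridge_field)
  expect_identical(a$pores, b$pores)

  # every pore duct opens on a ridge top
  for (s in 1:20) {
    m <- generate_skin_map(seed = s, resolution_um = 20)
    if (nrow(m$pores) > 0) {
      expect_true(all(ridge_at(m, m$pores$x, m$pores$y) >=
                        m$ridge_top_threshold))
    }
  }
})

test_that("pore counts follow the configured gland density", {
  # 350 glands/cm^2 on a 1320 um square -> lambda = 6.0998 per map; the
  # total over 200 maps is Poisson(1219.97), 99% interval ~ [1130, 1310]
  set.seed(123)
  lambda <- 350 * (1320 / 1e4)^2
  total <- sum(vapply(1:200, function(s) {
    nrow(generate_skin_map(seed = s, resolution_um = 44)$pores)
  }, numeric(1)))
  n <- 200 * lambda
  expect_gt(total, n - 2.576 * sqrt(n))
  expect_lt(total, n + 2.576 * sqrt(n))
})

test_that("impossible pore packing is rejected", {
  expect_error(
    generate_skin_map(gland_density_cm2 = 2e4, resolution_um = 20,
                      min_pore_spacing_um = 200, seed = 1),
    "density too high")
})

test_that("secretion kinetics saturate like washed skin reconstituting", {
  pore <- list(s_max = 2, tau = 15)
  expect_equal(secretion_level(0, pore), 0)
  expect_equal(secretion_level(15, pore), 2 * (1 - exp(-1)))
  expect_gte(secretion_level(5 * 15, pore), 0.993 * 2)
  # with tau = 15 min the level is essentially saturated after one hour
  expect_gte(secretion_level(60, pore), 0.98 * 2)

  t <- seq(0, 240, by = 5)
  s <- secretion_level(t, pore)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s <= pore$s_max))
  expect_error(secretion_level(-1, pore), "non-negative")
})

test_that("concentration fields are non-negative and track their drivers", {
  m <- toy_map()
  m <- add_pore(m, 220, 220, s_max = 1.5)
  f0 <- skin_concentration_fields(m, 0)
  f60 <- skin_concentration_fields(m, 60)
  for (f in c(f0, f60)) expect_true(all(f >= 0))
  expect_equal(max(f0$sodium_lactate), 0)
  expect_gt(max(f60$sodium_lactate), 1.4)
  # glucose field follows the attached profile
  m2 <- set_glucose_profile(m, function(t) 150)
  expect_equal(unique(as.numeric(
    skin_concentration_fields(m2, 10)$glucose)), 150 * m$kappa_glucose)
})
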