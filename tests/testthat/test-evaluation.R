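test_that("MARD and MAD reproduce hand computations", {
  expect_equal(mard(c(100, 50), c(100, 50))$value, 0)
  m <- mard(1.1 * c(80, 120, 200), c(80, 120, 200))
  expect_equal(m$value, 10)
  expect_equal(m$sd, 0)
  expect_equal(mard(c(110, 180, 55), c(100, 200, 50))$value, 10)

  expect_equal(mad_diff(c(7, 7), c(7, 7))$value, 0)
  expect_equal(mad_diff(c(105, 95, 105), c(100, 100, 100))$value, 5)
  expect_equal(mad_diff(c(90, 220), c(100, 200))$value, 15)

  expect_error(mard(c(1, 2), c(1, 0)), "positive")
  expect_error(mard(1:3, 1:2), "length mismatch")
  expect_error(mad_diff(1:3, 1:2), "length mismatch")
})

test_that("MARD is scale invariant, MAD scales, both ignore ordering", {
  set.seed(2)
  ref <- runif(20, 70, 250); pred <- ref * (1 + rnorm(20, 0, 0.1))
  o <- sample(20)
  expect_equal(mard(pred, ref)$value, mard(pred[o], ref[o])$value)
  expect_equal(mard(3 * pred, 3 * ref)$value, mard(pred, ref)$value)
  expect_equal(mad_diff(3 * pred, 3 * ref)$value, 3 * mad_diff(pred, ref)$value)
})

test_that("Clarke zones follow the piecewise rules with A-E-C-D-B precedence", {
  expect_equal(clarke_zone(100, 110), "A")
  expect_equal(clarke_zone(200, 60), "E")
  expect_equal(clarke_zone(60, 190), "E")
  expect_equal(clarke_zone(150, 265), "C")
  expect_equal(clarke_zone(170, 50), "C")   # pred <= 1.4*170 - 182 = 56
  expect_equal(clarke_zone(250, 100), "D")
  expect_equal(clarke_zone(60, 120), "D")
  expect_equal(clarke_zone(100, 130), "B")
  expect_equal(clarke_zone(65, 60), "A")    # both hypoglycemic

  # the diagonal always lies in zone A
  x <- seq(10, 400, by = 5)
  expect_true(all(clarke_zone(x, x) == "A"))

  # totality over a broad grid of pairs
  g <- expand.grid(ref = seq(10, 400, by = 13), pred = seq(10, 400, by = 13))
  z <- clarke_zone(g$ref, g$pred)
  expect_true(all(z %in% c("A", "B", "C", "D", "E")))

  expect_error(clarke_zone(0, 100), "positive")
})

test_that("zone tallies and fractions add up", {
  s <- clarke_summary(rep(100, 10), rep(100, 10))
  expect_equal(unname(s$counts["A"]), 10L)
  expect_equal(unname(s$fractions["A"]), 1)

  ref <- c(100, 80, 100, 150, 200)
  pred <- c(100, 90, 130, 265, 60)   # A, A, B, C, E by the stated rules
  s2 <- clarke_summary(ref, pred)
  expect_equal(unname(s2$counts), c(2L, 1L, 1L, 0L, 1L))
  expect_equal(sum(s2$fractions), 1, tolerance = 1e-9)
  expect_error(clarke_summary(numeric(0), numeric(0)), "empty")
})

test_that("evaluation reports assemble, pool and serialize consistently", {
  ref <- c(90, 120, 160, 200)
  rep1 <- evaluate_experiment(ref, ref)
  expect_equal(rep1$mard, 0)
  expect_equal(rep1$mad, 0)
  expect_equal(unname(rep1$zone_fractions["A"]), 1)
  expect_equal(sum(rep1$zone_counts), rep1$n_pairs)

  # pooled report equals the report over concatenated pairs, and its mean
  # metrics are the pair-count weighted means of the parts
  set.seed(5)
  r1 <- runif(10, 80, 200); p1 <- r1 * (1 + rnorm(10, 0, 0.08))
  r2 <- runif(15, 80, 200); p2 <- r2 * (1 + rnorm(15, 0, 0.12))
  pooled <- evaluate_experiment(c(p1, p2), c(r1, r2))
  e1 <- evaluate_experiment(p1, r1); e2 <- evaluate_experiment(p2, r2)
  expect_equal(pooled$mard, (10 * e1$mard + 15 * e2$mard) / 25)
  expect_equal(pooled$mad, (10 * e1$mad + 15 * e2$mad) / 25)
  expect_equal(pooled$zone_counts, e1$zone_counts + e2$zone_counts)

  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(pooled, path)
  back <- read_report_json(path)
  expect_equal(back$mard, pooled$mard)
  expect_equal(back$zone_counts, pooled$zone_counts)
  expect_equal(back$zone_fractions, pooled$zone_fractions)
  expect_equal(back$n_pairs, pooled$n_pairs)
})
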