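# random calibration-like fixture: spectra = mixture of smooth components
# plus noise, response linear in one component weight
sim_cal <- function(n, p, seed, noise = 0.05) {
  set.seed(seed)
  wn <- seq_len(p)
  comp <- rbind(exp(-(wn - p / 3)^2 / (2 * (p / 8)^2)),
                exp(-(wn - 2 * p / 3)^2 / (2 * (p / 10)^2)),
                0.5 + wn / (2 * p))
  conc <- cbind(runif(n, 0.5, 1.5), runif(n, 0, 1), runif(n, 0.8, 1.2))
  X <- conc %*% comp + matrix(rnorm(n * p, 0, noise), n, p)
  list(X = X, y = 100 + 50 * conc[, 1])
}

test_that("mean centering removes and restores the means", {
  d <- sim_cal(10, 40, 1)
  ctr <- mean_center(d$X, d$y)
  expect_lt(max(abs(colMeans(ctr$X))), 1e-10)
  expect_lt(abs(mean(ctr$y)), 1e-10)
  expect_equal(sweep(ctr$X, 2, ctr$x_mean, "+"), d$X)
  one <- mean_center(d$X[1, , drop = FALSE])
  expect_equal(unname(one$X), matrix(0, 1, 40))
})

test_that("PLSR and PCR at full rank match the least-squares oracle", {
  for (dims in list(c(12, 8), c(5, 20))) {
    d <- sim_cal(dims[1], dims[2], seed = sum(dims))
    ctr <- mean_center(d$X, d$y)
    r <- qr(ctr$X)$rank
    k <- min(dims[1] - 1, r)
    ls_fit <- drop(ctr$X %*% (pinv(ctr$X) %*% ctr$y)) + mean(d$y)

    pls <- fit_plsr(d$X, d$y, k)
    pcr <- fit_pcr(d$X, d$y, k)
    expect_equal(predict(pls, d$X), ls_fit, tolerance = 1e-6)
    expect_equal(predict(pcr, d$X), ls_fit, tolerance = 1e-6)
    expect_equal(predict(pls, d$X), predict(pcr, d$X), tolerance = 1e-6)
  }
})

test_that("a rank-one noiseless problem is solved by one latent variable", {
  t <- c(1, 2, 3, 4, 5)
  X <- outer(t, seq(0.1, 1, length.out = 12))
  y <- drop(X %*% rep(0.3, 12))
  m <- fit_plsr(X, y, 1)
  expect_lt(m$rmsec_by_lv[1], 1e-8)
})

test_that("NIPALS models are deterministic and internally consistent", {
  d <- sim_cal(15, 30, 7)
  m1 <- fit_plsr(d$X, d$y, 5)
  m2 <- fit_plsr(d$X, d$y, 5)
  expect_identical(m1, m2)

  # score orthogonality
  g <- crossprod(m1$T)
  expect_lt(max(abs(g - diag(diag(g)))) / max(diag(g)), 1e-8)
  # deflation residual orthogonal to extracted scores
  Xc <- mean_center(d$X)$X
  resid <- Xc - m1$T %*% t(m1$P)
  expect_lt(max(abs(crossprod(m1$T, resid))) / max(abs(Xc)), 1e-8)
  # coefficient predictions equal the factor recursion
  for (k in c(1, 3, 5)) {
    fac <- m1$y_mean + drop(m1$T[, 1:k, drop = FALSE] %*% m1$q[1:k])
    expect_equal(unname(m1$fitted_by_lv[, k]), fac, tolerance = 1e-8)
  }
})

test_that("requesting more components than the data support is rejected", {
  d <- sim_cal(5, 30, 3, noise = 0)
  expect_error(fit_plsr(d$X, d$y, 5), "at most")
  expect_error(fit_pcr(d$X, d$y, 5), "at most")
})

test_that("prediction applies centering and validates dimensions", {
  d <- sim_cal(10, 25, 5)
  m <- fit_plsr(d$X, d$y, 3)
  expect_equal(predict(m, d$X), unname(m$fitted_by_lv[, 3]))
  expect_equal(predict(m, m$x_mean), m$y_mean)
  expect_error(predict(m, d$X[, 1:10]), "wavenumbers")
})

test_that("PCR with one component ignores response-irrelevant variance", {
  set.seed(9)
  n <- 30
  v1 <- rnorm(n, 0, 10)            # dominant variance direction
  v2 <- rnorm(n, 0, 0.5)
  v2 <- residuals(lm(v2 ~ v1))     # exactly orthogonal to v1
  X <- cbind(v1, v2) %*% rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  y <- 100 + 5 * v2
  m <- fit_pcr(X, y, 1)
  expect_lt(stats::sd(predict(m, X)), 1e-6 * stats::sd(y))
  expect_equal(mean(predict(m, X)), mean(y), tolerance = 1e-6)
})

test_that("leave-one-out CV matches a manual-exclusion oracle at n = 5", {
  d <- sim_cal(5, 12, seed = 11)
  cv <- loo_cv(d$X, d$y, max_lv = 3)
  for (i in 1:5) {
    for (k in seq_len(cv$max_lv_used)) {
      m <- fit_plsr(d$X[-i, ], d$y[-i], k)
      expect_equal(cv$y_cv_by_lv[i, k], unname(predict(m, d$X[i, ], ncomp = k)),
                   tolerance = 1e-10)
    }
  }
  oracle_rmsecv <- sqrt(colMeans((cv$y_cv_by_lv - d$y)^2))
  expect_equal(cv$rmsecv_by_lv, oracle_rmsecv)
})

test_that("RMSEC decreases with components and duplicates give zero RMSE-CV", {
  d <- sim_cal(20, 40, 13)
  m <- fit_plsr(d$X, d$y, 8)
  expect_true(all(diff(m$rmsec_by_lv) <= 1e-10))

  base <- sim_cal(4, 15, 17, noise = 0)
  X <- base$X[rep(1:4, 3), ]
  y <- base$y[rep(1:4, 3)]
  cv <- suppressMessages(loo_cv(X, y, max_lv = 3))
  expect_lt(min(cv$rmsecv_by_lv), 1e-6 * mean(y))
})

test_that("latent-variable selection takes the RMSE-CV minimum, ties to fewer", {
  expect_identical(select_n_lv(c(5, 3, 3.5, 4)), 2L)
  expect_identical(select_n_lv(c(3, 3)), 1L)
  expect_message(chosen <- select_n_lv(c(5, 4, 3)), "still decreasing")
  expect_identical(chosen, 3L)
  expect_error(select_n_lv(numeric(0)), "empty")
})

test_that("infeasible candidate counts are capped with a note", {
  d <- sim_cal(5, 12, seed = 19)
  expect_message(cv <- loo_cv(d$X, d$y, max_lv = 10), "capped")
  expect_lte(cv$max_lv_used, 3)
  expect_error(loo_cv(d$X[1:2, ], d$y[1:2], 1), "at least 3")
})

test_that("PCR cross-validation shares the loo_cv contract", {
  d <- sim_cal(8, 20, 23)
  cv <- loo_cv(d$X, d$y, max_lv = 4, method = "pcr")
  for (i in c(1, 4, 8)) {
    m <- fit_pcr(d$X[-i, ], d$y[-i], cv$max_lv_used)
    expect_equal(cv$y_cv_by_lv[i, cv$max_lv_used],
                 unname(predict(m, d$X[i, ])), tolerance = 1e-10)
  }
})
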