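#' Mean-center a calibration block
#'
#' Subtracts the column means from the spectral block and the mean from
#' the reference values; the only preprocessing the calibration uses.
#'
#' @param X numeric matrix (samples x wavenumbers).
#' @param y optional numeric response.
#' @return list with centered `X`, centered `y`, `x_mean`, `y_mean`.
#' @export
mean_center <- function(X, y = NULL) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  out <- list(X = Xc, x_mean = x_mean)
  if (!is.null(y)) {
    out$y_mean <- mean(y)
    out$y <- y - out$y_mean
  }
  out
}

# NIPALS PLS1 on centered data; returns as many components as are
# numerically extractable, up to max_comp.
nipals_pls1 <- function(Xc, yc, max_comp, tol = 1e-12) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  Xd <- Xc; yd <- yc
  scale0 <- max(sqrt(sum(Xc^2)) * sqrt(sum(yc^2)), .Machine$double.eps)
  for (a in seq_len(max_comp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw <= tol * scale0) break
    w <- w / nw
    tv <- Xd %*% w
    tt <- sum(tv^2)
    if (tt <= tol * scale0) break
    pl <- crossprod(Xd, tv) / tt
    qa <- sum(yd * tv) / tt
    W <- cbind(W, w); P <- cbind(P, pl); Tm <- cbind(Tm, tv)
    q <- c(q, qa)
    Xd <- Xd - tv %*% t(pl)
    yd <- yd - qa * tv
  }
  list(W = W, P = P, T = Tm, q = q, n_comp = length(q))
}

# regression vectors for 1..n_comp components: b_k = W_k (P_k' W_k)^-1 q_k
pls_coefficients <- function(W, P, q) {
  k <- length(q)
  B <- matrix(0, nrow(W), k)
  for (a in seq_len(k)) {
    Wk <- W[, seq_len(a), drop = FALSE]
    Pk <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wk %*% solve(crossprod(Pk, Wk), q[seq_len(a)])
  }
  B
}

#' Fit a PLS1 calibration by NIPALS
#'
#' Partial least squares with a univariate response, computed by the
#' classical NIPALS recursion: each latent variable's weight vector is the
#' covariance direction `X'y` (normalized), scores are `t = Xw`, loadings
#' `p = X't/t't`, response loading `q = y't/t't`, and both blocks are
#' deflated before the next component. The regression vector for `k`
#' components is `b = W (P'W)^-1 q`.
#'
#' @param X spectra (samples x wavenumbers).
#' @param y reference glucose (mg/dl).
#' @param n_lv number of latent variables; must not exceed
#'   `min(n_samples - 1, rank of centered X)`.
#' @return a `plsr_model`: centering terms, `W`, `P`, `T`, `q`,
#'   per-count coefficient matrix `coefficients`, `fitted_by_lv`,
#'   `rmsec_by_lv`, `n_lv`.
#' @export
fit_plsr <- function(X, y, n_lv) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_lv >= 1)
  ctr <- mean_center(X, y)
  r <- qr(ctr$X)$rank
  attainable <- min(nrow(X) - 1, r)
  if (n_lv > attainable) {
    stop("n_lv = ", n_lv, " exceeds the usable rank; at most ", attainable,
         " latent variable(s) are attainable for this calibration set")
  }
  nip <- nipals_pls1(ctr$X, ctr$y, n_lv)
  if (nip$n_comp < n_lv) {
    stop("NIPALS became degenerate after ", nip$n_comp,
         " component(s); at most ", nip$n_comp, " are attainable")
  }
  B <- pls_coefficients(nip$W, nip$P, nip$q)
  fitted <- ctr$y_mean + apply(B, 2, function(b) ctr$X %*% b)
  rmsec <- sqrt(colMeans((fitted - y)^2))
  structure(list(x_mean = ctr$x_mean, y_mean = ctr$y_mean,
                 W = nip$W, P = nip$P, T = nip$T, q = nip$q,
                 coefficients = B, fitted_by_lv = fitted,
                 rmsec_by_lv = rmsec, n_lv = n_lv, method = "plsr"),
            class = c("plsr_model", "lv_model"))
}

#' Fit a principal component regression
#'
#' Singular value decomposition of the centered spectra; the response is
#' regressed on the leading principal-component scores. Shares the
#' prediction contract of [fit_plsr()].
#'
#' @inheritParams fit_plsr
#' @param n_pc number of principal components.
#' @return a `pcr_model` with the same fields as a `plsr_model` (scores in
#'   `T`, loadings in `P`).
#' @export
fit_pcr <- function(X, y, n_pc) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_pc >= 1)
  ctr <- mean_center(X, y)
  sv <- svd(ctr$X)
  pos <- sv$d > max(sv$d) * 1e-10
  attainable <- min(nrow(X) - 1, sum(pos))
  if (n_pc > attainable) {
    stop("n_pc = ", n_pc, " exceeds the usable rank; at most ", attainable,
         " component(s) are attainable for this calibration set")
  }
  gamma <- crossprod(sv$u[, seq_len(n_pc), drop = FALSE], ctr$y) /
    sv$d[seq_len(n_pc)]
  V <- sv$v[, seq_len(n_pc), drop = FALSE]
  B <- vapply(seq_len(n_pc), function(k) {
    V[, seq_len(k), drop = FALSE] %*% gamma[seq_len(k)]
  }, numeric(ncol(X)))
  B <- matrix(B, ncol = n_pc)
  fitted <- ctr$y_mean + apply(B, 2, function(b) ctr$X %*% b)
  rmsec <- sqrt(colMeans((fitted - y)^2))
  structure(list(x_mean = ctr$x_mean, y_mean = ctr$y_mean,
                 P = V, T = sv$u[, seq_len(n_pc), drop = FALSE] %*%
                   diag(sv$d[seq_len(n_pc)], n_pc),
                 q = as.numeric(gamma),
                 coefficients = B, fitted_by_lv = fitted,
                 rmsec_by_lv = rmsec, n_lv = n_pc, method = "pcr"),
            class = c("pcr_model", "lv_model"))
}

#' Predict glucose from spectra with a fitted latent-variable model
#'
#' @param object a `plsr_model` or `pcr_model`.
#' @param newdata spectra matrix (or a single spectrum vector) with the
#'   training wavenumber count.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return predicted glucose (mg/dl).
#' @export
predict.lv_model <- function(object, newdata, ncomp = object$n_lv, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " wavenumbers; model was trained on ",
         length(object$x_mean))
  }
  stopifnot(ncomp >= 1, ncomp <= object$n_lv)
  b <- object$coefficients[, ncomp]
  drop(sweep(newdata, 2, object$x_mean) %*% b + object$y_mean)
}

#' @export
print.lv_model <- function(x, ...) {
  cat(sprintf("<%s_model> %d latent variable(s), %d wavenumbers, RMSEC %.3g mg/dl\n",
              x$method, x$n_lv, length(x$x_mean),
              x$rmsec_by_lv[x$n_lv]))
  invisible(x)
}

#' Leave-one-out cross-validation of a latent-variable calibration
#'
#' For every held-out sample and every candidate component count the model
#' is refit on the remaining samples (re-centering inside each fold, so no
#' information leaks) and the held-out spectrum is predicted. Reports
#' RMSE-CV per candidate count, the calibration RMSEC curve from full-data
#' fits, and the selected count (global RMSE-CV minimum, smaller count on
#' ties).
#'
#' @param X spectra (samples x wavenumbers), at least 3 samples.
#' @param y reference glucose (mg/dl).
#' @param max_lv largest candidate component count; capped (with a note)
#'   at what every fold can support.
#' @param method `"plsr"` or `"pcr"`.
#' @return a `cv_result`: `y_cv_by_lv` (samples x counts), `y_cv` (at the
#'   chosen count), `rmsecv_by_lv`, `rmsec_by_lv`, `chosen_lv`,
#'   `max_lv_used`, `method`.
#' @export
loo_cv <- function(X, y, max_lv = 10, method = c("plsr", "pcr")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 samples")
  stopifnot(max_lv >= 1)

  fit_fold <- function(Xf, yf, k) {
    if (method == "plsr") {
      ctr <- mean_center(Xf, yf)
      nip <- nipals_pls1(ctr$X, ctr$y, k)
      list(ctr = ctr, B = pls_coefficients(nip$W, nip$P, nip$q),
           achieved = nip$n_comp)
    } else {
      ctr <- mean_center(Xf, yf)
      sv <- svd(ctr$X)
      pos <- sum(sv$d > max(sv$d) * 1e-10)
      kk <- min(k, pos, nrow(Xf) - 1)
      gamma <- crossprod(sv$u[, seq_len(kk), drop = FALSE], ctr$y) /
        sv$d[seq_len(kk)]
      V <- sv$v[, seq_len(kk), drop = FALSE]
      B <- vapply(seq_len(kk), function(a) {
        V[, seq_len(a), drop = FALSE] %*% gamma[seq_len(a)]
      }, numeric(ncol(Xf)))
      list(ctr = ctr, B = matrix(B, ncol = kk), achieved = kk)
    }
  }

  cap_req <- min(max_lv, n - 2)
  folds <- vector("list", n)
  achieved <- integer(n)
  for (i in seq_len(n)) {
    folds[[i]] <- fit_fold(X[-i, , drop = FALSE], y[-i], cap_req)
    achieved[i] <- folds[[i]]$achieved
  }
  cap <- min(achieved, cap_req)
  if (cap < max_lv) {
    message("candidate latent variables capped at ", cap,
            " (requested ", max_lv, ")")
  }
  y_cv <- matrix(NA_real_, n, cap)
  for (i in seq_len(n)) {
    f <- folds[[i]]
    xc <- X[i, ] - f$ctr$x_mean
    y_cv[i, ] <- f$ctr$y_mean +
      drop(xc %*% f$B[, seq_len(cap), drop = FALSE])
  }
  rmsecv <- sqrt(colMeans((y_cv - y)^2))
  full <- if (method == "plsr") fit_plsr(X, y, cap) else fit_pcr(X, y, cap)
  chosen <- select_n_lv(rmsecv)
  structure(list(y_cv_by_lv = y_cv, y_cv = y_cv[, chosen],
                 rmsecv_by_lv = rmsecv, rmsec_by_lv = full$rmsec_by_lv,
                 chosen_lv = chosen, max_lv_used = cap, method = method),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d candidate count(s); chosen %d (RMSE-CV %.3g mg/dl)\n",
              x$method, x$max_lv_used, x$chosen_lv,
              x$rmsecv_by_lv[x$chosen_lv]))
  invisible(x)
}

#' Select the latent-variable count from the RMSE-CV curve
#'
#' Global minimum of the cross-validation error curve; the smaller count
#' wins ties (parsimony). A curve that is still decreasing at its end
#' triggers a cautionary message, since the optimum may lie beyond the
#' candidate range.
#'
#' @param rmsecv_by_lv numeric RMSE-CV per candidate count (index = count).
#' @return selected count (integer).
#' @export
select_n_lv <- function(rmsecv_by_lv) {
  if (length(rmsecv_by_lv) == 0) stop("empty RMSE-CV curve")
  chosen <- which.min(rmsecv_by_lv)  # first index on ties
  k <- length(rmsecv_by_lv)
  if (chosen == k && k > 1 && all(diff(rmsecv_by_lv) < 0)) {
    message("RMSE-CV still decreasing at the largest candidate count (",
            k, "); consider widening the range")
  }
  as.integer(chosen)
}
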