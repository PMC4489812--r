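#' Latent-variable cap for PLS regression
#'
#' To avoid overfitting, the number of latent variables is capped at one tenth
#' of the number of observations: `floor(n / 10)`.
#'
#' @param n Number of observations.
#' @return The maximal admissible latent-variable count.
#' @export
plsr_lv_cap <- function(n) floor(n / 10)

#' Partial least squares regression (NIPALS)
#'
#' PLS1 regression on mean-centered data via the NIPALS algorithm: for each
#' latent variable the weight is `w = X'y` (normalized), the score `t = Xw`,
#' the loadings `p = X't/(t't)` and `q = y't/(t't)`, after which `X` and `y`
#' are deflated. Successive score vectors are orthogonal by construction. The
#' regression vector `B = W (P'W)^{-1} q` reproduces the staged predictions in
#' one matrix product.
#'
#' @param X Numeric matrix, samples x channels.
#' @param y Numeric response vector.
#' @param n_lv Number of latent variables.
#' @param enforce_lv_cap Enforce `n_lv <= floor(n/10)` ([plsr_lv_cap()]);
#'   disable only for small algebraic checks.
#' @return An object of class `plsr_model`.
#' @export
fit_plsr <- function(X, y, n_lv = 2, enforce_lv_cap = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n_lv < 1) abort("fit_plsr: n_lv must be >= 1")
  if (enforce_lv_cap && n_lv > plsr_lv_cap(n)) {
    abort(paste0("fit_plsr: n_lv exceeds the overfitting cap floor(n/10) = ",
                 plsr_lv_cap(n)))
  }
  if (sd(y) < 1e-12) abort("fit_plsr: constant response is degenerate")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  p <- ncol(X)
  W <- P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort(paste0("fit_plsr: X carries no covariance with y at component ", a))
    }
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    P[, a] <- drop(crossprod(Xc, t)) / tt
    q[a] <- sum(yc * t) / tt
    W[, a] <- w
    Tm[, a] <- t
    Xc <- Xc - tcrossprod(t, P[, a])
    yc <- yc - t * q[a]
  }
  beta <- W %*% solve(crossprod(P, W), q)
  structure(list(n_lv = n_lv, x_weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, regression_vector = drop(beta),
                 x_mean = x_mean, y_mean = y_mean),
            class = "plsr_model")
}

#' Predict from a PLS regression model
#'
#' `y_hat = y_mean + (X - x_mean) %*% regression_vector`.
#'
#' @param model A `plsr_model`.
#' @param X New sample matrix with matching channels.
#' @return Numeric vector of predictions.
#' @export
predict_plsr <- function(model, X) {
  X <- as.matrix(X)
  drop(model$y_mean + sweep(X, 2, model$x_mean) %*% model$regression_vector)
}

#' @export
predict.plsr_model <- function(object, newdata, ...) predict_plsr(object, newdata)

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s), %d channels\n",
              x$n_lv, length(x$regression_vector)))
  invisible(x)
}

#' @rdname tidy.nir_pca
#' @export
tidy.plsr_model <- function(x, ...) {
  tibble::tibble(channel = names(x$x_mean) %||%
                   as.character(seq_along(x$x_mean)),
                 regression_vector = x$regression_vector)
}

# Two-block NIPALS PLS (PLS2) on centered matrices; the inner engine of
# OPLS-DA. Started from the first response column; iterates w <- X'u,
# t <- Xw, q <- Y't, u <- Yq to convergence (tol on score change, max 500
# iterations, warning on non-convergence).
fit_pls2_core <- function(Xc, Yc, n_lv, tol = 1e-10, max_iter = 500) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  m <- ncol(Yc)
  W <- P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv)
  Tm <- matrix(0, n, n_lv)
  for (a in seq_len(n_lv)) {
    u <- Yc[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      w <- w / sqrt(sum(w^2))
      t <- drop(Xc %*% w)
      qv <- drop(crossprod(Yc, t))
      qv <- qv / sqrt(sum(qv^2))
      u <- drop(Yc %*% qv)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    if (it == max_iter) {
      warn("fit_pls2_core: NIPALS did not converge; using best iterate")
    }
    tt <- sum(t^2)
    P[, a] <- drop(crossprod(Xc, t)) / tt
    Q[, a] <- drop(crossprod(Yc, t)) / tt
    W[, a] <- w
    Tm[, a] <- t
    Xc <- Xc - tcrossprod(t, P[, a])
    Yc <- Yc - tcrossprod(t, Q[, a])
  }
  beta <- W %*% solve(crossprod(P, W), t(Q))
  list(x_weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
       coefficients = beta)
}

#' Regression quality metrics
#'
#' `rmse = sqrt(mean((y - y_hat)^2))` and `r2 = 1 - SS_res / SS_tot`. The
#' `context` label distinguishes calibration (RMSEC), cross-validation
#' (RMSECV) and external prediction (RMSEP) in reports.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @param context One of `"calibration"`, `"cv"`, `"prediction"`.
#' @return A tibble with `context`, `r2`, `rmse`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred,
                               context = c("calibration", "cv", "prediction")) {
  context <- match.arg(context)
  stopifnot(length(y_true) == length(y_pred))
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  tibble::tibble(context = context,
                 r2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(ss_res / length(y_true)),
                 n = length(y_true))
}
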