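test_that("PCA matches the SVD oracle and its variance bookkeeping closes", {
  X <- withr::with_seed(11, matrix(rnorm(24), 6, 4))
  m <- fit_pca(X, k = 3)
  ref <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    s <- sign(sum(m$loadings[, j] * ref$rotation[, j]))
    expect_equal(m$loadings[, j], s * unname(ref$rotation[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(m$scores[, j], s * unname(ref$x[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(sum(m$explained_variance_pct), 100)
  expect_true(all(diff(m$explained_variance_pct) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(m$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading element positive
  for (j in 1:3) expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
})

test_that("PCA handles rank-1 data, channel reordering and bad k", {
  u <- withr::with_seed(12, rnorm(9))
  v <- withr::with_seed(13, rnorm(5))
  X <- u %o% v
  m <- fit_pca(X, 1)
  expect_equal(m$explained_variance_pct[1], 100)
  # reordering channels permutes loadings but not variances or score geometry
  X2 <- withr::with_seed(14, matrix(rnorm(40), 8, 5))
  perm <- c(3, 1, 5, 2, 4)
  m1 <- fit_pca(X2, 2)
  m2 <- fit_pca(X2[, perm], 2)
  expect_equal(m1$explained_variance_pct, m2$explained_variance_pct)
  expect_equal(abs(m1$scores), abs(m2$scores), tolerance = 1e-8)
  expect_error(fit_pca(X2, 8), "k must be")
  # projection of training data reproduces the scores
  expect_equal(predict(m1, X2), m1$scores, tolerance = 1e-10)
})

test_that("PLSR solves exact low-rank problems and is capped against overfitting", {
  # y exactly linear in one channel of an orthogonal design, noiseless, 1 LV
  X <- withr::with_seed(21,
    qr.Q(qr(scale(matrix(rnorm(200 * 5), 200), scale = FALSE))) * 10)
  y <- 3 * X[, 2] + 1
  m <- fit_plsr(X, y, 1)
  expect_lt(sqrt(mean((predict_plsr(m, X) - y)^2)), 1e-10)
  # the overfitting cap is floor(n/10)
  expect_equal(plsr_lv_cap(150), 15)
  expect_error(fit_plsr(X, y, 21), "cap")
  expect_error(fit_plsr(X, rep(1, 200), 1), "constant")
  # full-rank small system equals ordinary least squares
  X8 <- withr::with_seed(22, matrix(rnorm(24), 8, 3))
  y8 <- withr::with_seed(23, rnorm(8))
  mf <- fit_plsr(X8, y8, 3, enforce_lv_cap = FALSE)
  ols <- lm.fit(cbind(1, X8), y8)
  expect_equal(predict_plsr(mf, X8), unname(ols$fitted.values),
               tolerance = 1e-8)
  # successive score vectors orthogonal
  expect_lt(max(abs(crossprod(mf$scores) - diag(diag(crossprod(mf$scores))))),
            1e-8)
})

test_that("PLSR prediction is a pure affine map of the spectra", {
  X <- withr::with_seed(24, matrix(rnorm(60 * 6), 60))
  y <- withr::with_seed(25, X %*% rnorm(6) + rnorm(60, sd = 0.1))
  m <- fit_plsr(X, drop(y), 2)
  # channel permutation with matching model permutation leaves yhat unchanged
  perm <- sample(6)
  m2 <- m
  m2$regression_vector <- m$regression_vector[perm]
  m2$x_mean <- m$x_mean[perm]
  expect_equal(predict_plsr(m2, X[, perm]), predict_plsr(m, X))
  # hand-computed 2-channel example
  Xh <- cbind(c(1, 2, 3, 4), c(0, 1, 0, 1))
  yh <- c(1, 3, 3, 5)  # y = 2*x1 + ... exactly linear
  mh <- fit_plsr(Xh, yh, 2, enforce_lv_cap = FALSE)
  bh <- solve(crossprod(cbind(1, Xh)), crossprod(cbind(1, Xh), yh))
  expect_equal(predict_plsr(mh, Xh), drop(cbind(1, Xh) %*% bh),
               tolerance = 1e-8)
})

test_that("PLSR agrees with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  X <- withr::with_seed(26, matrix(rnorm(40 * 12), 40,
                                   dimnames = list(NULL, paste0("ch", 1:12))))
  y <- withr::with_seed(27, drop(X %*% rnorm(12)) + rnorm(40))
  ours <- fit_plsr(X, y, 3, enforce_lv_cap = FALSE)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(predict_plsr(ours, X), unname(pref), tolerance = 1e-6)
})

test_that("regression metrics follow their definitions", {
  expect_equal(regression_metrics(1:5, 1:5)$rmse, 0)
  expect_equal(regression_metrics(1:5, 1:5)$r2, 1)
  expect_equal(regression_metrics(1:5, rep(3, 5))$r2, 0)
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4), context = "cv")
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$context, "cv")
})

test_that("OPLS-DA with zero orthogonal components reduces to PLS2-DA", {
  sim <- simulate_experiment(cfg_window(wl_step = 10))
  X <- spectra_matrix(sim$spectra)
  g <- sim$spectra$group
  m0 <- fit_oplsda(X, g, n_predictive = 2, n_orthogonal = 0)
  pred0 <- predict_oplsda(m0, X)
  skip_if_not_installed("mixOmics")
  ref <- mixOmics::plsda(X, factor(g), ncomp = 2, scale = FALSE)
  Yref <- predict(ref, X)$predict[, , 2]
  expect_equal(unname(as.matrix(pred0[paste0("score_", sort(unique(g)))])),
               unname(Yref[, sort(unique(g))]), tolerance = 1e-6)
})

test_that("the orthogonal filter removes structured class-orthogonal variance", {
  # 3 classes with pairwise mean separations of 5 sigma on two channels,
  # plus a strong class-orthogonal confound
  withr::with_seed(31, {
    n <- 60
    cls <- rep(c("a", "b", "c"), each = n / 3)
    conf <- rnorm(n, sd = 10)          # orthogonal confound, 10x the signal
    X <- cbind(signal1 = c(a = 0, b = 5, c = 5)[cls] + rnorm(n),
               signal2 = c(a = 0, b = 0, c = 5)[cls] + rnorm(n),
               confound = conf,
               matrix(rnorm(n * 6), n))
  })
  m <- fit_oplsda(X, cls, n_predictive = 2, n_orthogonal = 1)
  # perfect training classification
  expect_equal(predict_oplsda(m, X)$predicted, unname(cls))
  # orthogonal scores uncorrelated with every dummy column
  Y <- class_dummy(cls)
  for (j in 1:3) {
    expect_lt(abs(cor(m$orthogonal_scores[, 1], Y[, j])), 1e-8)
  }
  # planted orthogonal variance (10x) exceeds the first predictive component
  expect_gt(m$orthogonal_x_variance_pct[1], m$predictive_x_variance_pct[1])
  # refiltering an (essentially noise-free) filtered matrix finds almost
  # nothing left: structured orthogonal variance is removed in one pass
  clsq <- rep(c("a", "b", "c"), each = 10)
  withr::with_seed(33, {
    t_conf <- rnorm(30)
    t_conf <- unname(residuals(lm(t_conf ~ clsq)))  # exactly class-orthogonal
    Xq <- cbind(c(a = 0, b = 3, c = 6)[clsq],
                matrix(rnorm(30 * 4, sd = 1e-3), 30)) +
      t_conf %o% c(0.2, 1, 1, 0.5, 0.3)
  })
  mq <- fit_oplsda(Xq, clsq, 2, 1)
  Xf <- probionir:::oplsda_filter(mq, sweep(Xq, 2, mq$x_mean))
  m2 <- fit_oplsda(sweep(Xf, 2, -mq$x_mean), clsq, 2, 1)
  leftover <- if (m2$n_orthogonal > 0) m2$orthogonal_x_variance_pct[1] else 0
  expect_lt(leftover, 0.1)
})

test_that("OPLS-DA prediction contract: centroids, ties, empty input, errors", {
  withr::with_seed(32, {
    cls <- rep(c("a", "b", "c"), each = 10)
    centroids <- rbind(a = c(5, 0, 0), b = c(0, 5, 0), c = c(0, 0, 5))
    X <- centroids[cls, ] + matrix(rnorm(90, sd = 0.2), 30)
  })
  m <- fit_oplsda(X, cls, n_predictive = 2, n_orthogonal = 1)
  expect_equal(predict_oplsda(m, centroids["b", , drop = FALSE])$predicted, "b")
  empty <- predict_oplsda(m, X[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("predicted", "score_a", "score_b", "score_c"))
  expect_error(fit_oplsda(X, rep("a", 30)), "at least 2 classes")
  expect_error(fit_oplsda(X[1:11, ], c(rep("a", 10), "b")), "< 2 samples")
  expect_equal(rowSums(class_dummy(cls)), rep(1, 30))
})

test_that("all latent-variable fits are deterministic given input order", {
  sim <- simulate_experiment(cfg_window(wl_step = 10))
  X <- spectra_matrix(sim$spectra)
  g <- sim$spectra$group
  y <- as.numeric(factor(g))
  expect_identical(fit_oplsda(X, g), fit_oplsda(X, g))
  expect_identical(fit_plsr(X, y, 2), fit_plsr(X, y, 2))
  expect_identical(fit_pca(X, 3), fit_pca(X, 3))
})
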