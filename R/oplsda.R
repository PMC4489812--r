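#' One-hot class encoding
#'
#' @param labels Character or factor vector of class labels.
#' @param classes Ordered class set; defaults to the sorted unique labels.
#' @return A matrix with one row per sample, one column per class; rows sum
#'   to 1.
#' @export
class_dummy <- function(labels, classes = sort(unique(as.character(labels)))) {
  labels <- as.character(labels)
  if (!all(labels %in% classes)) abort("class_dummy: label outside class set")
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' OPLS-DA separates the predictive variation of `X` (correlated with class
#' membership) from structured variation orthogonal to it. Per orthogonal
#' component the Trygg-Wold filter computes the predictive weight space from
#' the singular vectors of `X'Y` (mean-centered one-hot `Y`), takes the
#' loading `p` of the dominant predictive score, orthogonalizes it against
#' the full predictive weight space, and deflates `X` by the resulting
#' orthogonal component. A PLS2 discriminant model with `n_predictive` latent
#' variables is then fitted on the filtered matrix. By construction the
#' orthogonal scores have zero sample correlation with every class-membership
#' column.
#'
#' @param X Numeric matrix, samples x channels.
#' @param labels Class labels; at least 2 classes with >= 2 samples each.
#' @param n_predictive Predictive latent variables (default: classes - 1).
#' @param n_orthogonal Orthogonal components to remove (default 1; may be 0).
#' @return An object of class `oplsda_model` with the orthogonal filter
#'   (`orthogonal_weights`, `orthogonal_loadings`, `orthogonal_scores`), the
#'   inner PLS2-DA fit, and the percent of X-variance captured by each
#'   predictive and orthogonal component.
#' @export
fit_oplsda <- function(X, labels, n_predictive = NULL, n_orthogonal = 1) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("fit_oplsda: need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(paste0("fit_oplsda: class with < 2 samples: ",
                 names(counts)[which(counts < 2)[1]]))
  }
  n_predictive <- n_predictive %||% (length(classes) - 1L)
  Y <- class_dummy(labels, classes)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  ssx <- sum(Xc^2)
  p <- ncol(X)
  Wo <- Po <- matrix(0, p, 0)
  To <- matrix(0, nrow(X), 0)
  orth_var <- numeric(0)
  for (i in seq_len(n_orthogonal)) {
    sv <- svd(crossprod(Xc, Yc))
    keep <- sv$d > 1e-12 * sv$d[1]
    Wp <- sv$u[, keep, drop = FALSE]
    w1 <- Wp[, 1]
    t1 <- drop(Xc %*% w1)
    pl <- drop(crossprod(Xc, t1)) / sum(t1^2)
    w_orth <- pl - Wp %*% crossprod(Wp, pl)
    nw <- sqrt(sum(w_orth^2))
    if (nw < 1e-12) break
    w_orth <- drop(w_orth) / nw
    if (w_orth[which.max(abs(w_orth))] < 0) w_orth <- -w_orth
    t_orth <- drop(Xc %*% w_orth)
    p_orth <- drop(crossprod(Xc, t_orth)) / sum(t_orth^2)
    Xc <- Xc - tcrossprod(t_orth, p_orth)
    Wo <- cbind(Wo, w_orth)
    Po <- cbind(Po, p_orth)
    To <- cbind(To, t_orth)
    orth_var <- c(orth_var, 100 * sum(t_orth^2) * sum(p_orth^2) / ssx)
  }
  inner <- fit_pls2_core(Xc, Yc, n_predictive)
  for (a in seq_len(n_predictive)) {
    w <- inner$x_weights[, a]
    if (w[which.max(abs(w))] < 0) {
      inner$x_weights[, a] <- -w
      inner$x_loadings[, a] <- -inner$x_loadings[, a]
      inner$y_loadings[, a] <- -inner$y_loadings[, a]
      inner$scores[, a] <- -inner$scores[, a]
    }
  }
  pred_var <- vapply(seq_len(n_predictive), function(a) {
    100 * sum(inner$scores[, a]^2) * sum(inner$x_loadings[, a]^2) / ssx
  }, numeric(1))
  structure(list(class_labels = classes,
                 n_predictive = n_predictive,
                 n_orthogonal = ncol(Wo),
                 orthogonal_weights = Wo, orthogonal_loadings = Po,
                 orthogonal_scores = To,
                 inner = inner,
                 predictive_x_variance_pct = pred_var,
                 orthogonal_x_variance_pct = orth_var,
                 x_mean = x_mean, y_mean = y_mean),
            class = "oplsda_model")
}

# Pass new (centered) spectra through the stored orthogonal filter.
oplsda_filter <- function(model, Xc) {
  for (i in seq_len(model$n_orthogonal)) {
    t_orth <- drop(Xc %*% model$orthogonal_weights[, i])
    Xc <- Xc - tcrossprod(t_orth, model$orthogonal_loadings[, i])
  }
  Xc
}

#' Predict classes from an OPLS-DA model
#'
#' New spectra are centered, passed through the stored orthogonal filter,
#' and scored by the inner PLS2-DA model; the assigned class is the argmax
#' of the predicted class-membership values. Ties are broken by class order
#' with a warning.
#'
#' @param model An `oplsda_model`.
#' @param X New sample matrix (may have zero rows).
#' @return A tibble with `predicted` and one `score_<class>` column per
#'   class.
#' @export
predict_oplsda <- function(model, X) {
  X <- as.matrix(X)
  cls <- model$class_labels
  if (nrow(X) == 0) {
    out <- tibble::tibble(predicted = character(0))
    for (cl in cls) out[[paste0("score_", cl)]] <- numeric(0)
    return(out)
  }
  Xf <- oplsda_filter(model, sweep(X, 2, model$x_mean))
  Yhat <- Xf %*% model$inner$coefficients
  Yhat <- sweep(Yhat, 2, model$y_mean, "+")
  idx <- apply(Yhat, 1, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1) warn("predict_oplsda: tie broken by class order")
    top[1]
  })
  out <- tibble::tibble(predicted = cls[idx])
  for (j in seq_along(cls)) out[[paste0("score_", cls[j])]] <- Yhat[, j]
  out
}

#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  predict_oplsda(object, newdata)
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "<oplsda_model> classes: %s; %d predictive (%s%% X-var), %d orthogonal (%s%% X-var)\n",
    paste(x$class_labels, collapse = ", "),
    x$n_predictive,
    paste(sprintf("%.2f", x$predictive_x_variance_pct), collapse = ", "),
    x$n_orthogonal,
    if (x$n_orthogonal > 0)
      paste(sprintf("%.2f", x$orthogonal_x_variance_pct), collapse = ", ")
    else "-"))
  invisible(x)
}

#' @rdname tidy.nir_pca
#' @export
glance.oplsda_model <- function(x, ...) {
  tibble::tibble(
    component = c(paste0("predictive_", seq_len(x$n_predictive)),
                  if (x$n_orthogonal > 0)
                    paste0("orthogonal_", seq_len(x$n_orthogonal))),
    x_variance_pct = c(x$predictive_x_variance_pct,
                       x$orthogonal_x_variance_pct))
}

#' Score plot for an OPLS-DA model
#'
#' Plots the first two predictive score vectors (the two discriminant
#' functions for a three-group problem), coloured by class.
#'
#' @param object An `oplsda_model`.
#' @param labels Optional true labels for colouring (defaults to none).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oplsda_model <- function(object, labels = NULL, ...) {
  s <- object$inner$scores
  if (ncol(s) < 2) abort("autoplot.oplsda_model: needs >= 2 predictive LVs")
  df <- tibble::tibble(t1 = s[, 1], t2 = s[, 2])
  lab <- function(i) sprintf("Discriminant function %d (%.1f%% X-var)", i,
                             object$predictive_x_variance_pct[i])
  if (!is.null(labels)) {
    df$class <- as.character(labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$t1, .data$t2,
                                          colour = .data$class))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$t1, .data$t2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}
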