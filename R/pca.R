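#' Principal component analysis
#'
#' Mean-centered PCA via singular value decomposition. Scores are the centered
#' data projected on the loadings; `explained_variance_pct` is reported for
#' every possible component (it sums to 100 over the full rank), while
#' `loadings`/`scores` keep the first `k`. Loading signs follow the convention
#' that each loading's largest-magnitude element is positive, which makes
#' plots and tests reproducible.
#'
#' @param X Numeric matrix, samples x channels.
#' @param k Number of components to retain; at most `min(n - 1, p)`.
#' @return An object of class `nir_pca` with fields `loadings` (p x k),
#'   `scores` (n x k), `explained_variance_pct` (full rank), `column_mean`,
#'   `n_components`.
#' @export
fit_pca <- function(X, k = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (k < 1 || k > kmax) {
    abort(paste0("fit_pca: k must be between 1 and min(n-1, p) = ", kmax))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  lam <- sv$d^2
  expl <- 100 * lam[seq_len(kmax)] / sum(lam[seq_len(kmax)])
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(n_components = k, loadings = loadings, scores = scores,
                 explained_variance_pct = expl, column_mean = mu),
            class = "nir_pca")
}

#' Project new samples onto a fitted PCA
#'
#' @param object A `nir_pca` model.
#' @param newdata Matrix with the same channels as the training data.
#' @param ... Unused.
#' @return A score matrix (samples x components).
#' @export
predict.nir_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$column_mean) %*% object$loadings
}

#' @export
print.nir_pca <- function(x, ...) {
  cat(sprintf("<nir_pca> %d component(s); explained variance: %s%%\n",
              x$n_components,
              paste(sprintf("%.1f", head(x$explained_variance_pct,
                                         x$n_components)), collapse = ", ")))
  invisible(x)
}

#' Tidiers for PCA models
#'
#' `tidy()` returns scores (`matrix = "scores"`) or loadings
#' (`matrix = "loadings"`) in long-friendly tibbles; `glance()` returns the
#' per-component explained variance.
#'
#' @param x A `nir_pca` model.
#' @param matrix `"scores"` or `"loadings"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nir_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  out <- tibble::as_tibble(m)
  if (matrix == "loadings") {
    out <- dplyr::bind_cols(
      tibble::tibble(channel = rownames(x$loadings) %||%
                       as.character(seq_len(nrow(x$loadings)))), out)
  } else {
    out <- dplyr::bind_cols(tibble::tibble(row = seq_len(nrow(m))), out)
  }
  out
}

#' @rdname tidy.nir_pca
#' @export
glance.nir_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_variance_pct),
                 explained_variance_pct = x$explained_variance_pct,
                 cumulative_pct = cumsum(x$explained_variance_pct))
}

#' Score plot for a fitted PCA
#'
#' @param object A `nir_pca` model.
#' @param plane Integer pair of components to plot.
#' @param colour Optional vector (e.g. group labels) colouring the points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nir_pca <- function(object, plane = c(1, 2), colour = NULL, ...) {
  df <- tibble::tibble(x = object$scores[, plane[1]],
                       y = object$scores[, plane[2]])
  lab <- function(i) sprintf("PC%d (%.1f%%)", i,
                             object$explained_variance_pct[i])
  if (!is.null(colour)) {
    df$colour <- colour
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          colour = .data$colour))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab(plane[1]), y = lab(plane[2]), colour = NULL) +
    ggplot2::theme_minimal()
}
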