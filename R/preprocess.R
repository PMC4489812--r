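#' Savitzky-Golay smoothing
#'
#' Smooths each spectrum (row) with a moving least-squares polynomial filter.
#' At the edges the polynomial is fitted on the truncated one-sided window, so
#' no absorbance is fabricated beyond the measured range.
#'
#' @param spectra Numeric matrix, scans x channels.
#' @param window Odd window length in points (default 21).
#' @param order Polynomial order (default 2); must be < `window`.
#' @return Smoothed matrix of the same shape.
#' @export
savgol_smooth <- function(spectra, window = 21, order = 2) {
  spectra <- as.matrix(spectra)
  p <- ncol(spectra)
  if (window %% 2 == 0) abort("savgol_smooth: window must be odd")
  if (window <= order) abort("savgol_smooth: window must exceed the order")
  if (window > p) abort("savgol_smooth: window longer than the spectrum")
  spectra %*% t(savgol_matrix(p, window, order))
}

# Linear filter matrix: row i gives the weights producing the smoothed value
# at channel i. Interior rows share the classical SG convolution kernel;
# edge rows come from a least-squares fit on the clipped window.
savgol_matrix <- function(p, window, order) {
  half <- (window - 1L) / 2L
  W <- matrix(0, p, p)
  kern <- savgol_row_weights(-half:half, 0L, order)
  for (i in seq_len(p)) {
    lo <- max(1L, i - half)
    hi <- min(p, i + half)
    if (lo == i - half && hi == i + half) {
      W[i, lo:hi] <- kern
    } else {
      W[i, lo:hi] <- savgol_row_weights(lo:hi - i, 0L, order)
    }
  }
  W
}

# Weights w such that w %*% y = fitted polynomial value at offset `at`,
# for a least-squares polynomial of degree `order` on offsets `off`.
savgol_row_weights <- function(off, at, order) {
  A <- outer(off, 0:order, "^")
  a0 <- at^(0:order)
  drop(a0 %*% solve(crossprod(A), t(A)))
}

#' Multiplicative scatter correction
#'
#' `fit_msc()` stores the reference spectrum (the column-wise mean of the
#' training spectra). `apply_msc()` regresses every spectrum on that reference
#' (`x ~ a + b * reference` by ordinary least squares over channels) and
#' returns `(x - a) / b`, removing per-scan multiplicative gain and additive
#' offset exactly for affine distortions of the reference shape.
#'
#' @param training Numeric matrix of training spectra.
#' @param spectra Numeric matrix to correct.
#' @param reference Reference spectrum (from `fit_msc()`).
#' @param tol Degeneracy tolerance on the fitted gain `b`.
#' @return `fit_msc()` a numeric vector; `apply_msc()` a corrected matrix.
#' @export
fit_msc <- function(training) {
  colMeans(as.matrix(training))
}

#' @rdname fit_msc
#' @export
apply_msc <- function(spectra, reference, tol = 1e-12) {
  spectra <- as.matrix(spectra)
  r <- as.numeric(reference)
  stopifnot(ncol(spectra) == length(r))
  rc <- r - mean(r)
  ss <- sum(rc^2)
  if (ss < tol) abort("apply_msc: reference spectrum has no variance")
  b <- as.numeric(spectra %*% rc) / ss
  if (any(abs(b) < tol)) {
    abort(paste0("apply_msc: degenerate spectrum (|b| < tol) at row ",
                 which(abs(b) < tol)[1]))
  }
  a <- rowMeans(spectra) - b * mean(r)
  (spectra - a) / b
}

#' Pareto scaling
#'
#' `fit_pareto()` returns per-channel training mean and sample standard
#' deviation (denominator n-1); `apply_pareto()` maps column j to
#' `(x - mean_j) / sqrt(sd_j)` - a milder compression than autoscaling that
#' keeps large spectral features visible while damping noise channels.
#' Channels with `sd < tol` are mapped to 0.
#'
#' @param training Numeric training matrix.
#' @param spectra Matrix to transform.
#' @param center,scale_sd Per-channel mean and SD from `fit_pareto()`.
#' @param tol Degenerate-column tolerance.
#' @return `fit_pareto()` a list with `mean` and `sd`; `apply_pareto()` a
#'   matrix.
#' @export
fit_pareto <- function(training) {
  training <- as.matrix(training)
  list(mean = colMeans(training), sd = apply(training, 2, sd))
}

#' @rdname fit_pareto
#' @export
apply_pareto <- function(spectra, center, scale_sd, tol = 1e-12) {
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(center), length(center) == length(scale_sd))
  out <- sweep(spectra, 2, center, "-")
  keep <- scale_sd >= tol
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2, sqrt(scale_sd[keep]), "/")
  out[, !keep] <- 0
  out
}

#' Preprocessing configuration
#'
#' @param sg_window,sg_order Savitzky-Golay window (odd points) and order.
#' @param apply_msc Apply multiplicative scatter correction.
#' @param scaling `"pareto"` or `"none"`.
#' @return A list of class `preprocess_cfg`.
#' @export
preprocess_cfg <- function(sg_window = 21, sg_order = 2,
                           apply_msc = TRUE, scaling = c("pareto", "none")) {
  scaling <- match.arg(scaling)
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 apply_msc = apply_msc, scaling = scaling),
            class = "preprocess_cfg")
}

#' Fit and apply the preprocessing chain
#'
#' The fixed chain is Savitzky-Golay smoothing (per spectrum), multiplicative
#' scatter correction, then Pareto scaling. `preprocess_fit()` estimates the
#' MSC reference and the Pareto statistics on the training spectra only;
#' `preprocess_apply()` transforms any dataset with those frozen statistics,
#' so held-out strains never leak into the fitted state.
#'
#' @param train A spectral dataset used to estimate the statistics.
#' @param ds A spectral dataset to transform.
#' @param cfg A [preprocess_cfg()].
#' @param model A fitted `preprocess_model`.
#' @return `preprocess_fit()` a `preprocess_model`; `preprocess_apply()` the
#'   transformed dataset; `preprocess_fit_apply()` a list with elements
#'   `model`, `train` and (if given) `test`.
#' @export
preprocess_fit <- function(train, cfg = preprocess_cfg()) {
  x <- savgol_smooth(spectra_matrix(train), cfg$sg_window, cfg$sg_order)
  ref <- NULL
  if (cfg$apply_msc) {
    ref <- fit_msc(x)
    x <- apply_msc(x, ref)
  }
  par <- NULL
  if (cfg$scaling == "pareto") par <- fit_pareto(x)
  structure(list(cfg = cfg, wavelengths = wavelengths(train),
                 msc_reference = ref,
                 pareto_mean = par$mean, pareto_sd = par$sd),
            class = "preprocess_model")
}

#' @rdname preprocess_fit
#' @export
preprocess_apply <- function(ds, model) {
  wl <- wavelengths(ds)
  if (length(wl) != length(model$wavelengths) ||
      any(abs(wl - model$wavelengths) > 1e-9)) {
    abort("preprocess_apply: wavelength axis does not match the fitted model")
  }
  x <- savgol_smooth(spectra_matrix(ds), model$cfg$sg_window, model$cfg$sg_order)
  if (!is.null(model$msc_reference)) x <- apply_msc(x, model$msc_reference)
  if (!is.null(model$pareto_mean)) {
    x <- apply_pareto(x, model$pareto_mean, model$pareto_sd)
  }
  set_spectra_matrix(ds, x)
}

#' @rdname preprocess_fit
#' @param test Optional held-out dataset transformed with the training
#'   statistics.
#' @export
preprocess_fit_apply <- function(train, test = NULL, cfg = preprocess_cfg()) {
  model <- preprocess_fit(train, cfg)
  out <- list(model = model, train = preprocess_apply(train, model))
  if (!is.null(test)) out$test <- preprocess_apply(test, model)
  out
}
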