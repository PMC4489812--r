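#' Pairwise group-separation ratio in a score plane
#'
#' For each pair of groups the ratio is the Euclidean distance between the
#' group centres divided by the sum of the two groups' spreads, where the
#' spread is the root-mean-square Euclidean distance of a group's points to
#' its centre in the plane. The ratio is invariant under rotation,
#' translation and uniform scaling of the plane.
#'
#' @param scores Numeric matrix with two columns (the score plane).
#' @param groups Group label per row; every group needs >= 2 points.
#' @return A tibble with `group_a`, `group_b`, `ratio`.
#' @export
separation_ratio <- function(scores, groups) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, nrow(scores) == length(groups))
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (length(gs) < 2) abort("separation_ratio: need >= 2 groups")
  counts <- table(groups)
  if (any(counts < 2)) {
    abort(paste0("separation_ratio: group with < 2 points: ",
                 names(counts)[which(counts < 2)[1]]))
  }
  centres <- lapply(gs, function(g) colMeans(scores[groups == g, , drop = FALSE]))
  spreads <- vapply(seq_along(gs), function(i) {
    pts <- scores[groups == gs[i], , drop = FALSE]
    d2 <- sweep(pts, 2, centres[[i]])
    sqrt(mean(rowSums(d2^2)))
  }, numeric(1))
  pairs <- utils::combn(seq_along(gs), 2)
  tibble::tibble(
    group_a = gs[pairs[1, ]],
    group_b = gs[pairs[2, ]],
    ratio = vapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      sqrt(sum((centres[[i]] - centres[[j]])^2)) / (spreads[i] + spreads[j])
    }, numeric(1)))
}

#' Moving-window PCA over cultivation time
#'
#' Slides a window of `window_len` consecutive scans along each strain's time
#' course; at each position the window's spectra from all strains are pooled,
#' preprocessed (statistics refit on the window), decomposed by PCA, and the
#' pairwise group-separation ratios are computed on the chosen score plane.
#' With `N` aligned scans per strain the scan covers window starts
#' `0 ... N - window_len - 1`, i.e. `N - window_len` windows (300 scans with
#' a 10-scan window give 290 PCA models).
#'
#' The default plane is (PC2, PC3): in growth-monitoring spectra PC1 is
#' dominated by the slow temperature-driven drift of the water spectrum, so
#' group structure shows up on the later components.
#'
#' @param ds A spectral dataset; every strain must have the same number of
#'   scans with identical time stamps.
#' @param window_len Window length in scans (default 10).
#' @param plane Integer pair of PCA components (default `c(2, 3)`).
#' @param cfg Preprocessing configuration for the per-window refit.
#' @return An object of class `window_scan` with per-window ratios
#'   (`$ratios`, long), the min-pair summary (`$windows`) and the selected
#'   optimal window (`$selected`).
#' @export
moving_window_pca <- function(ds, window_len = 10, plane = c(2, 3),
                              cfg = preprocess_cfg()) {
  meta <- spectra_meta(ds)
  strains <- unique(meta$strain_id)
  times <- lapply(strains, function(s) meta$time_min[meta$strain_id == s])
  n0 <- length(times[[1]])
  for (i in seq_along(strains)) {
    if (length(times[[i]]) != n0 ||
        any(abs(times[[i]] - times[[1]]) > 1e-6)) {
      abort(paste0("moving_window_pca: strain not aligned with the others: ",
                   strains[i]))
    }
  }
  if (window_len >= n0) {
    abort("moving_window_pca: need more scans per strain than window_len")
  }
  n_windows <- n0 - window_len
  scan_index <- stats::ave(meta$time_min, meta$strain_id,
                           FUN = seq_along)
  res <- vector("list", n_windows)
  for (s in seq_len(n_windows)) {
    keep <- scan_index >= s & scan_index <= s + window_len - 1
    win <- ds[keep, ]
    pp <- preprocess_fit_apply(win, cfg = cfg)
    pca <- fit_pca(spectra_matrix(pp$train), k = max(plane))
    rat <- separation_ratio(pca$scores[, plane], spectra_meta(win)$group)
    rat$window <- s
    rat$t_start <- times[[1]][s]
    rat$t_end <- times[[1]][s + window_len - 1]
    res[[s]] <- rat
  }
  ratios <- dplyr::bind_rows(res)
  windows <- ratios |>
    dplyr::group_by(.data$window, .data$t_start, .data$t_end) |>
    dplyr::summarise(min_ratio = min(.data$ratio), .groups = "drop") |>
    dplyr::arrange(.data$window)
  out <- structure(list(ratios = ratios, windows = windows,
                        window_len = window_len, plane = plane,
                        selected = NULL),
                   class = "window_scan")
  out$selected <- select_optimal_window(out)
  out
}

#' Select the optimal analysis window
#'
#' The optimal window maximizes the minimum pairwise separation ratio, i.e.
#' the window where every pair of groups is simultaneously well separated.
#' Ties pick the earliest window and emit a message.
#'
#' @param res A `window_scan` result.
#' @return A list with `window`, `t_start`, `t_end`, `min_ratio`.
#' @export
select_optimal_window <- function(res) {
  w <- res$windows
  best <- max(w$min_ratio)
  hits <- which(w$min_ratio >= best - 1e-12)
  if (length(hits) > 1) {
    inform(paste0("select_optimal_window: ", length(hits),
                  " tied windows; keeping the earliest"))
  }
  i <- hits[1]
  list(window = w$window[i], t_start = w$t_start[i], t_end = w$t_end[i],
       min_ratio = w$min_ratio[i])
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf(
    "<window_scan> %d windows of %d scans on plane (PC%d, PC%d)\n",
    nrow(x$windows), x$window_len, x$plane[1], x$plane[2]))
  cat(sprintf("  optimal window: %.0f-%.0f min (min pairwise ratio %.3f)\n",
              x$selected$t_start, x$selected$t_end, x$selected$min_ratio))
  invisible(x)
}

#' @rdname tidy.nir_pca
#' @export
tidy.window_scan <- function(x, ...) {
  dplyr::left_join(x$ratios,
                   x$windows[c("window", "min_ratio")], by = "window") |>
    dplyr::relocate("window", "t_start", "t_end")
}

#' Ratio-versus-time plot for a window scan
#'
#' @param object A `window_scan` result.
#' @param ... Unused.
#' @return A ggplot object: one line per group pair plus the min-pair curve,
#'   the selected window marked.
#' @export
autoplot.window_scan <- function(object, ...) {
  r <- object$ratios
  r$pair <- paste(r$group_a, r$group_b, sep = " vs ")
  ggplot2::ggplot(r, ggplot2::aes(.data$t_start / 60, .data$ratio,
                                  colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = object$windows,
                       ggplot2::aes(.data$t_start / 60, .data$min_ratio),
                       colour = "black", linetype = 2,
                       inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = object$selected$t_start / 60,
                        linetype = 3) +
    ggplot2::labs(x = "cultivation time (h)", y = "separation ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
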