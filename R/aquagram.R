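#' Water matrix coordinates (WAMACs)
#'
#' The characteristic wavelengths of the first overtone of water used for
#' aquagram fingerprints, each assigned to a water molecular species:
#' protonated water clusters of increasing size (1342, 1374, 1486 nm),
#' hydration-shell OH stretch of OH- clusters (1364, 1440, 1452 nm),
#' H2O-OH bonded water (1384 nm), free water S0 (1412 nm), protein-bound
#' water (1426 nm) and the S2/S3 bonded-water clusters (1462, 1476 nm).
#'
#' @return A tibble with `wavelength_nm` and `label`, 11 coordinates within
#'   1342-1486 nm.
#' @export
default_wamacs <- function() {
  tibble::tribble(
    ~wavelength_nm, ~label,
    1342, "protonated cluster H+(H2O)3",
    1364, "hydration shell OH-(H2O)2",
    1374, "protonated cluster H+(H2O)4,5",
    1384, "H2O-OH bonded water",
    1412, "free water S0",
    1426, "protein-bound water",
    1440, "hydration shell OH-(H2O)4",
    1452, "hydration shell OH-(H2O)5",
    1462, "bonded water S2 (H2O)3",
    1476, "bonded water S3 (H2O)4",
    1486, "protonated cluster H+(H2O)6,7"
  )
}

#' Aquagram profiles at the water matrix coordinates
#'
#' For each WAMAC the nearest wavelength channel is taken, absorbance is
#' z-scored across all spectra of the comparison set (`a' = (a - mean) / sd`
#' per wavelength), and the profile value of a group is the mean of `a'`
#' over the group's spectra. The size-weighted mean of the group profiles is
#' therefore 0 at every coordinate when the groups partition the comparison
#' set. Spectra should be smoothed and scatter-corrected (Savitzky-Golay +
#' MSC) and restricted to the analysis time window first; an external
#' reference such as pure (mQ) water can be passed as an extra pseudo-group
#' using the `reference` argument.
#'
#' @param ds A spectral dataset (preprocessed through SG + MSC).
#' @param wamacs A WAMAC table, by default [default_wamacs()].
#' @param reference Optional matrix of reference spectra on the same
#'   wavelength axis, included as pseudo-group `"reference"`.
#' @return A tibble with `group`, `wamac_nm`, `label`, `value`.
#' @export
compute_aquagram <- function(ds, wamacs = default_wamacs(), reference = NULL) {
  wl <- wavelengths(ds)
  x <- spectra_matrix(ds)
  groups <- spectra_meta(ds)$group
  if (!is.null(reference)) {
    reference <- as.matrix(reference)
    stopifnot(ncol(reference) == length(wl))
    x <- rbind(x, reference)
    groups <- c(groups, rep("reference", nrow(reference)))
  }
  if (any(table(groups) < 2)) {
    abort("compute_aquagram: every group needs >= 2 spectra")
  }
  step <- if (length(wl) > 1) min(diff(wl)) else Inf
  idx <- vapply(wamacs$wavelength_nm, function(w) {
    i <- which.min(abs(wl - w))
    if (abs(wl[i] - w) > step) {
      abort(paste0("compute_aquagram: no channel within one step of ", w,
                   " nm"))
    }
    i
  }, integer(1))
  sub <- x[, idx, drop = FALSE]
  mu <- colMeans(sub)
  sdev <- apply(sub, 2, sd)
  z <- sweep(sweep(sub, 2, mu), 2, sdev, "/")
  purrr::map_dfr(sort(unique(groups)), function(g) {
    tibble::tibble(group = g,
                   wamac_nm = wamacs$wavelength_nm,
                   label = wamacs$label,
                   value = colMeans(z[groups == g, , drop = FALSE]))
  })
}

#' Radar (aquagram) chart of WAMAC profiles
#'
#' @param profiles Output of [compute_aquagram()].
#' @return A ggplot object on polar coordinates, one line per group.
#' @export
plot_aquagram <- function(profiles) {
  profiles$axis <- factor(profiles$wamac_nm)
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$axis, .data$value, colour = .data$group,
                               group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "normalized absorbance", colour = NULL) +
    ggplot2::theme_minimal()
}
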