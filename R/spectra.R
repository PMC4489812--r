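#' Spectral dataset container
#'
#' A `nir_spectra` object is a tibble holding one scan per row: the metadata
#' columns `strain_id`, `group` and `time_min`, followed by one absorbance
#' column per wavelength channel, named by its wavelength in nm (e.g. `"1100"`,
#' `"1100.5"`). `nir_spectra()` validates a data frame and stamps the class;
#' all analysis functions in the package accept either a validated object or a
#' plain data frame with the same layout.
#'
#' Invariants enforced: wavelengths strictly increasing on a uniform grid;
#' every row carries a `strain_id` and a finite `time_min >= 0`; absorbance
#' values are finite; rows of one strain are sorted by time (the constructor
#' applies a stable sort by `(strain_id, time_min)`).
#'
#' @param x A data frame with columns `strain_id`, `group`, `time_min` and
#'   numerically named wavelength columns.
#' @return A tibble of class `nir_spectra`.
#' @examples
#' ds <- nir_spectra(tibble::tibble(
#'   strain_id = c("A", "A"), group = "probiotic", time_min = c(40, 44),
#'   `1100` = c(0.5, 0.6), `1100.5` = c(0.7, 0.8)
#' ))
#' wavelengths(ds)
#' @export
nir_spectra <- function(x) {
  x <- tibble::as_tibble(x, .name_repair = "minimal")
  meta_cols <- c("strain_id", "group", "time_min")
  missing_meta <- setdiff(meta_cols, names(x))
  if (length(missing_meta) > 0) {
    abort(paste0("format error: missing metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  wl <- parse_wavelength_names(x)
  if (length(wl) < 1) abort("format error: no wavelength columns found")
  dup <- names(wl)[duplicated(wl)]
  if (length(dup) > 0) {
    abort(paste0("format error: duplicated wavelength column: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(diff(wl) <= 0)) {
    abort("format error: wavelengths must be strictly increasing")
  }
  if (length(wl) > 2) {
    steps <- diff(wl)
    if (max(steps) - min(steps) > 1e-6 * max(steps)) {
      abort("format error: wavelength grid must have a uniform step")
    }
  }
  if (!is.numeric(x$time_min) || anyNA(x$time_min) ||
      any(!is.finite(x$time_min)) || any(x$time_min < 0)) {
    abort("format error: time_min must be finite and >= 0 for every row")
  }
  if (anyNA(x$strain_id) || any(x$strain_id == "")) {
    abort("format error: every row needs a strain_id")
  }
  ok_groups <- c("probiotic", "moderate", "non_probiotic", "unknown")
  if (!all(x$group %in% ok_groups)) {
    abort(paste0("format error: group labels must be one of: ",
                 paste(ok_groups, collapse = ", ")))
  }
  a <- as.matrix(x[names(wl)])
  bad <- which(!is.finite(a), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("format error: non-finite absorbance at row ", bad[1, 1],
                 ", wavelength ", names(wl)[bad[1, 2]]))
  }
  x <- x[order(x$strain_id, x$time_min, method = "radix"),
         c(meta_cols, setdiff(names(x), c(meta_cols, names(wl))), names(wl))]
  class(x) <- c("nir_spectra", class(tibble::tibble()))
  x
}

parse_wavelength_names <- function(x) {
  suppressWarnings(v <- as.numeric(names(x)))
  keep <- is.finite(v)
  setNames(v[keep], names(x)[keep])
}

#' Accessors for spectral datasets
#'
#' `wavelengths()` returns the wavelength axis (nm), `spectra_matrix()` the
#' absorbance matrix (scans x channels), and `spectra_meta()` the metadata
#' columns.
#'
#' @param ds A `nir_spectra` tibble (or data frame with the same layout).
#' @return A numeric vector, matrix, or tibble respectively.
#' @export
wavelengths <- function(ds) {
  unname(parse_wavelength_names(ds))
}

#' @rdname wavelengths
#' @export
spectra_matrix <- function(ds) {
  wl <- parse_wavelength_names(ds)
  m <- as.matrix(ds[names(wl)])
  dimnames(m) <- list(NULL, names(wl))
  m
}

#' @rdname wavelengths
#' @export
spectra_meta <- function(ds) {
  wl <- parse_wavelength_names(ds)
  tibble::as_tibble(ds[setdiff(names(ds), names(wl))])
}

#' Replace the absorbance block of a dataset
#'
#' Used by preprocessing steps: keeps metadata and wavelength names, swaps in
#' a transformed absorbance matrix of the same shape.
#'
#' @param ds A spectral dataset.
#' @param m A numeric matrix with `nrow(ds)` rows and one column per channel.
#' @return A dataset of the same class and layout.
#' @export
set_spectra_matrix <- function(ds, m) {
  wl <- parse_wavelength_names(ds)
  stopifnot(nrow(m) == nrow(ds), ncol(m) == length(wl))
  ds[names(wl)] <- tibble::as_tibble(`colnames<-`(m, names(wl)))
  ds
}

#' Read and write spectral data tables
#'
#' Plain delimited text with a header row: metadata columns `strain_id`,
#' `group`, `time_min` first, then one column per wavelength named by its nm
#' value. The delimiter is auto-detected from the file extension (`.csv` =
#' comma, anything else = tab). Values round-trip at full double precision.
#'
#' @param path File path.
#' @param ds A spectral dataset (for `write_spectra()`).
#' @return `read_spectra()` returns a validated `nir_spectra` tibble;
#'   `write_spectra()` returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- read_delim_auto(path)
  nir_spectra(x)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(ds, path) {
  write_delim_auto(tibble::as_tibble(ds), path)
  invisible(path)
}

read_delim_auto <- function(path) {
  # base strtod parsing is correctly rounded, so %.17g output round-trips
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tibble::as_tibble(
    utils::read.delim(path, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    .name_repair = "minimal")
}

write_delim_auto <- function(x, path) {
  # format doubles with 17 significant digits so values round-trip exactly
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], function(v) sub("^\\s+", "", sprintf("%.17g", v)))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
}

#' Truncate a dataset to a wavelength range
#'
#' Keeps channels with `lo <= lambda <= hi` (closed interval); metadata are
#' untouched. The working range for the growth-monitoring analyses is
#' 1100-1850 nm, the region containing the first overtone of water.
#'
#' @param ds A spectral dataset.
#' @param lo,hi Wavelength bounds in nm, `lo < hi` (or `lo == hi` to pick a
#'   single channel).
#' @return The truncated dataset.
#' @export
truncate_wavelengths <- function(ds, lo = 1100, hi = 1850) {
  if (lo > hi) abort("truncate_wavelengths: lo must be <= hi")
  wl <- parse_wavelength_names(ds)
  keep <- names(wl)[wl >= lo & wl <= hi]
  if (length(keep) == 0) {
    abort("truncate_wavelengths: no channels in the requested range")
  }
  ds[c(setdiff(names(ds), names(wl)), keep)]
}

#' Select a cultivation-time window
#'
#' Keeps scans with `t_lo <= time_min <= t_hi` (closed interval); per-strain
#' time ordering is preserved. May return an empty dataset. The optimal
#' analysis window found by moving-window PCA for the probiotic screening
#' problem is 11.4-12 h (684-720 min), ten scans per strain at the 4-min
#' cadence.
#'
#' @param ds A spectral dataset.
#' @param t_lo,t_hi Time bounds. Minutes by default; hours if `hours = TRUE`.
#' @param hours Interpret `t_lo`/`t_hi` as hours.
#' @return The windowed dataset.
#' @export
select_time_window <- function(ds, t_lo, t_hi, hours = FALSE) {
  if (hours) {
    t_lo <- t_lo * 60
    t_hi <- t_hi * 60
  }
  if (t_lo > t_hi) abort("select_time_window: t_lo must be <= t_hi")
  ds[ds$time_min >= t_lo & ds$time_min <= t_hi, ]
}

#' @export
print.nir_spectra <- function(x, ...) {
  wl <- parse_wavelength_names(x)
  cat(sprintf(
    "<nir_spectra> %d scans x %d channels (%.1f-%.1f nm), %d strain(s)\n",
    nrow(x), length(wl), min(wl), max(wl), length(unique(x$strain_id))))
  NextMethod()
}
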