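#' Reference phenotype table of the 18 Lactobacillus strains
#'
#' The wet-lab reference phenotype of each strain in the screening study:
#' maximal specific growth rate in MRS broth (`mu_max`, 1/h), maximal optical
#' density at 665 nm (`od_max`), minimal inhibitory bile concentration
#' (`bile_mic`, mg/ml) and yield of biomass after 3 h at pH 1.8 with pepsin
#' (`acid_yield`, delta OD665 after 24 h regrowth). Strains are labelled
#' probiotic, moderate or non-probiotic by these four criteria.
#'
#' Fifteen strains (five per group) form the modelling set; `S08`, `SR` and
#' `SS` were reserved for independent validation of the spectral models and
#' are returned only with `model_set = FALSE`.
#'
#' @param model_set If `TRUE` (default) return only the 15 modelling strains;
#'   if `FALSE`, all 18.
#' @return A tibble with columns `strain_id`, `group`, `mu_max`, `od_max`,
#'   `bile_mic`, `acid_yield`.
#' @examples
#' lactobacillus_phenotypes()
#' @export
lactobacillus_phenotypes <- function(model_set = TRUE) {
  pt <- tibble::tribble(
    ~strain_id, ~group,          ~mu_max, ~od_max, ~bile_mic, ~acid_yield,
    "S10",      "probiotic",       0.115,   2.950,     2.500,       0.126,
    "S11",      "probiotic",       0.118,   2.950,     2.500,       0.100,
    "S20",      "probiotic",       0.304,   3.030,     2.500,       0.114,
    "S22",      "probiotic",       0.106,   2.677,     2.500,       0.117,
    "S06",      "probiotic",       0.301,   2.960,     1.250,       0.080,
    "S01",      "moderate",        0.121,   1.692,     0.625,       0.038,
    "S07",      "moderate",        0.075,   1.919,     0.625,       0.049,
    "S28",      "moderate",        0.106,   2.770,     0.313,       0.025,
    "S09",      "moderate",        0.118,   2.880,     0.156,       0.029,
    "Y12",      "moderate",        0.150,   2.023,     0.625,       0.041,
    "S02",      "non_probiotic",   0.070,   1.521,     0.156,       0.006,
    "S03",      "non_probiotic",   0.060,   1.343,     0.313,       0.005,
    "S04",      "non_probiotic",   0.060,   0.841,     0.156,       0.007,
    "S29",      "non_probiotic",   0.060,   1.440,     0.625,       0.005,
    "S30",      "non_probiotic",   0.050,   1.360,     0.625,       0.006,
    "S08",      "moderate",        0.080,   2.940,     0.625,       0.049,
    "SR",       "probiotic",       0.070,   1.676,     1.250,       0.036,
    "SS",       "probiotic",       0.220,   2.963,     2.250,       0.107
  )
  if (model_set) pt <- pt[1:15, ]
  validate_phenotypes(pt)
}

#' Validate, read and write a phenotype table
#'
#' A phenotype table has one row per strain with `strain_id`, `group` and the
#' four numeric reference variables `mu_max`, `od_max`, `bile_mic`,
#' `acid_yield`, all non-negative; `strain_id` must be unique.
#'
#' @param pt A data frame in phenotype-table layout.
#' @param path File path (delimiter auto-detected from extension).
#' @return A validated tibble (or `path` invisibly for the writer).
#' @export
validate_phenotypes <- function(pt) {
  pt <- tibble::as_tibble(pt)
  need <- c("strain_id", "group", "mu_max", "od_max", "bile_mic", "acid_yield")
  missing <- setdiff(need, names(pt))
  if (length(missing) > 0) {
    abort(paste0("phenotype table: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(pt$strain_id)) {
    abort("phenotype table: strain_id must be unique")
  }
  num <- c("mu_max", "od_max", "bile_mic", "acid_yield")
  v <- as.matrix(pt[num])
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
    abort("phenotype table: numeric variables must be finite and >= 0")
  }
  pt[c(need, setdiff(names(pt), need))]
}

#' @rdname validate_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_phenotypes(read_delim_auto(path))
}

#' @rdname validate_phenotypes
#' @export
write_phenotypes <- function(pt, path) {
  write_delim_auto(tibble::as_tibble(pt), path)
  invisible(path)
}
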