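#' One-strain-out data splits
#'
#' One fold per distinct strain: all spectra of that strain form the test
#' set and the remaining strains the training set, so the evaluation measures
#' strain-level generalization rather than scan-level interpolation. Folds
#' are ordered by `strain_id`; the union of the test sets is the whole
#' dataset.
#'
#' @param ds A spectral dataset with >= 2 strains.
#' @return A list of folds, each a list with `strain`, `train`, `test`.
#' @export
one_strain_out_split <- function(ds) {
  strains <- sort(unique(ds$strain_id))
  if (length(strains) < 2) {
    abort("one_strain_out_split: need >= 2 strains to form folds")
  }
  lapply(strains, function(s) {
    list(strain = s,
         train = ds[ds$strain_id != s, ],
         test = ds[ds$strain_id == s, ])
  })
}

#' One-strain-out cross-validation of the OPLS-DA classifier
#'
#' Per fold the preprocessing statistics and the OPLS-DA model are fitted on
#' the training strains only, then the held-out strain's spectra are
#' transformed and classified. A strain-level call is the majority vote over
#' the strain's spectra (ties give `NA` with a message). The report carries
#' spectrum- and strain-level accuracy and the confusion matrix.
#'
#' @param ds A spectral dataset restricted to the analysis time window.
#' @param n_predictive,n_orthogonal OPLS-DA component counts.
#' @param cfg Preprocessing configuration (refit inside every fold).
#' @return An object of class `validation_report`.
#' @export
cross_validate_classifier <- function(ds, n_predictive = NULL,
                                      n_orthogonal = 1,
                                      cfg = preprocess_cfg()) {
  if (length(unique(ds$group)) < 2) {
    abort("cross_validate_classifier: need >= 2 groups; single-group data is degenerate")
  }
  folds <- one_strain_out_split(ds)
  spectrum <- purrr::map_dfr(folds, function(f) {
    pp <- preprocess_fit_apply(f$train, f$test, cfg)
    model <- fit_oplsda(spectra_matrix(pp$train), spectra_meta(pp$train)$group,
                        n_predictive, n_orthogonal)
    pred <- predict_oplsda(model, spectra_matrix(pp$test))
    dplyr::bind_cols(
      spectra_meta(pp$test)[c("strain_id", "group", "time_min")], pred)
  })
  build_classification_report(spectrum)
}

build_classification_report <- function(spectrum) {
  strain <- spectrum |>
    dplyr::group_by(.data$strain_id, .data$group) |>
    dplyr::summarise(predicted = majority_vote(.data$predicted),
                     .groups = "drop")
  classes <- sort(unique(c(spectrum$group, spectrum$predicted)))
  confusion <- table(factor(spectrum$group, classes),
                     factor(spectrum$predicted, classes))
  names(dimnames(confusion)) <- c("true", "predicted")
  structure(list(
    spectrum = spectrum,
    strain = strain,
    confusion = confusion,
    accuracy_spectrum = 100 * mean(spectrum$predicted == spectrum$group),
    accuracy_strain = 100 * mean(!is.na(strain$predicted) &
                                   strain$predicted == strain$group)),
    class = "validation_report")
}

majority_vote <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    inform("majority_vote: tie; strain left unclassified")
    return(NA_character_)
  }
  names(tab)[1]
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %.1f%% of spectra, %.1f%% of strains correctly classified\n",
    x$accuracy_spectrum, x$accuracy_strain))
  print(x$confusion)
  invisible(x)
}

#' @rdname tidy.nir_pca
#' @export
tidy.validation_report <- function(x, ...) x$spectrum

#' @rdname tidy.nir_pca
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(accuracy_spectrum_pct = x$accuracy_spectrum,
                 accuracy_strain_pct = x$accuracy_strain,
                 n_spectra = nrow(x$spectrum),
                 n_strains = nrow(x$strain))
}

#' One-strain-out cross-validation of a PLSR model
#'
#' The per-strain target value is broadcast to the strain's spectra. Per fold
#' a PLSR model is fitted on the training strains (preprocessing refit on the
#' fold) and the held-out strain's spectra are predicted, giving a per-strain
#' RMSEP; the pooled held-out residuals give RMSECV, and a full-data fit
#' gives the calibration R2/RMSEC.
#'
#' @param ds A spectral dataset restricted to the analysis window.
#' @param targets A data frame with `strain_id` and `value` (one row per
#'   strain).
#' @param n_lv Latent variables (default 2).
#' @param cfg Preprocessing configuration.
#' @return An object of class `regression_cv` with `$per_strain` (RMSEP per
#'   held-out strain), `$metrics` (calibration and cross-validation rows) and
#'   `$predictions`.
#' @export
cross_validate_regressor <- function(ds, targets, n_lv = 2,
                                     cfg = preprocess_cfg()) {
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("strain_id", "value") %in% names(targets)))
  if (sd(targets$value) < 1e-12) {
    abort("cross_validate_regressor: constant target is degenerate")
  }
  y_of <- setNames(targets$value, targets$strain_id)
  if (!all(ds$strain_id %in% names(y_of))) {
    abort("cross_validate_regressor: target missing for some strain")
  }
  folds <- one_strain_out_split(ds)
  preds <- purrr::map_dfr(folds, function(f) {
    pp <- preprocess_fit_apply(f$train, f$test, cfg)
    model <- fit_plsr(spectra_matrix(pp$train),
                      y_of[spectra_meta(pp$train)$strain_id], n_lv)
    tibble::tibble(strain_id = f$strain,
                   y_true = unname(y_of[spectra_meta(pp$test)$strain_id]),
                   y_pred = predict_plsr(model, spectra_matrix(pp$test)))
  })
  per_strain <- preds |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(rmsep = sqrt(mean((.data$y_true - .data$y_pred)^2)),
                     .groups = "drop")
  pp_full <- preprocess_fit_apply(ds, cfg = cfg)
  full <- fit_plsr(spectra_matrix(pp_full$train), y_of[ds$strain_id], n_lv)
  y_cal <- predict_plsr(full, spectra_matrix(pp_full$train))
  metrics <- dplyr::bind_rows(
    regression_metrics(unname(y_of[ds$strain_id]), y_cal, "calibration"),
    regression_metrics(preds$y_true, preds$y_pred, "cv"))
  structure(list(per_strain = per_strain, metrics = metrics,
                 predictions = preds, model = full),
            class = "regression_cv")
}

#' @export
print.regression_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<regression_cv> R2tr %.4f, RMSEC %.4g | R2cv %.4f, RMSECV %.4g\n",
    m$r2[1], m$rmse[1], m$r2[2], m$rmse[2]))
  invisible(x)
}

#' @rdname tidy.nir_pca
#' @export
glance.regression_cv <- function(x, ...) {
  tidyr::pivot_wider(x$metrics, names_from = "context",
                     values_from = c("r2", "rmse", "n"))
}

#' Independent hold-out validation of the classifier
#'
#' Fits preprocessing and OPLS-DA on all training strains, then classifies
#' each held-out strain's spectra and reports the per-strain breakdown of
#' spectrum-level assignments (e.g. a 70%/30% split between two groups).
#'
#' @param train_ds,test_ds Training and held-out spectral datasets.
#' @param n_predictive,n_orthogonal OPLS-DA component counts.
#' @param cfg Preprocessing configuration.
#' @return A list with the fitted `model`, spectrum-level `assignments` and
#'   the per-strain `fractions` tibble (strain, predicted group, percent of
#'   the strain's spectra).
#' @export
independent_validation <- function(train_ds, test_ds, n_predictive = NULL,
                                   n_orthogonal = 1, cfg = preprocess_cfg()) {
  pp <- preprocess_fit_apply(train_ds, test_ds, cfg)
  model <- fit_oplsda(spectra_matrix(pp$train), spectra_meta(pp$train)$group,
                      n_predictive, n_orthogonal)
  if (nrow(test_ds) == 0) {
    return(list(model = model,
                assignments = tibble::tibble(strain_id = character(0),
                                             group = character(0),
                                             predicted = character(0)),
                fractions = tibble::tibble(strain_id = character(0),
                                           predicted = character(0),
                                           pct = numeric(0))))
  }
  pred <- predict_oplsda(model, spectra_matrix(pp$test))
  assignments <- dplyr::bind_cols(
    spectra_meta(pp$test)[c("strain_id", "group", "time_min")], pred)
  fractions <- assignments |>
    dplyr::count(.data$strain_id, .data$predicted) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(model = model, assignments = assignments, fractions = fractions)
}
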