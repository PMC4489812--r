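#' Run the full screening pipeline
#'
#' Orchestrates the end-to-end study replication on one configuration:
#' load (or simulate) the spectra and phenotype tables, truncate to the
#' working wavelength range, scan cultivation time with moving-window PCA,
#' select the optimal analysis window, classify the groups with one-strain-out
#' OPLS-DA (plus independent validation if hold-out strains are named),
#' regress bile MIC and acid-stress yield with PLSR, and compute the aquagram
#' profiles and the reference-PCA probioticity scores. Per-stage artifacts
#' are written to the output directory as delimited text together with a run
#' log listing every resolved parameter; any stage failure aborts with the
#' stage name while earlier artifacts are retained.
#'
#' @param config A configuration list, or path to a YAML file with the same
#'   keys. Recognised keys (all optional unless stated): `spectra` /
#'   `phenotypes` (paths; if absent a simulation is run with `seed`), `seed`,
#'   `out_dir` (required), `holdout_strains` (character vector),
#'   `wl_lo`, `wl_hi`, `window_len`, `plane`, `sg_window`, `sg_order`,
#'   `n_predictive`, `n_orthogonal`, `n_lv`, `window` (`c(t_lo, t_hi)` in
#'   minutes to skip the scan), `scan_step_min` (coarsen the scan grid),
#'   `regress` (logical, default TRUE).
#' @return Invisibly, a list with every stage result.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort("config error: out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    logf("[stage] %s", name)
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  cfg_get <- function(key, default) config[[key]] %||% default
  pcfg <- preprocess_cfg(sg_window = cfg_get("sg_window", 21),
                         sg_order = cfg_get("sg_order", 2))
  for (k in setdiff(names(config), "out_dir")) {
    logf("config: %s = %s", k, paste(format(config[[k]]), collapse = ", "))
  }

  res <- list()
  res$inputs <- stage("load", {
    if (!is.null(config$spectra)) {
      list(spectra = read_spectra(config$spectra),
           phenotypes = if (!is.null(config$phenotypes))
             read_phenotypes(config$phenotypes))
    } else {
      sim <- simulate_experiment(sim_config(seed = cfg_get("seed", 1)))
      jsonlite::write_json(
        sim$truth[c("strains", "bands", "phenotype_links", "peak_window")],
        file.path(config$out_dir, "truth.json"), auto_unbox = TRUE,
        digits = NA)
      list(spectra = sim$spectra, phenotypes = sim$phenotypes)
    }
  })
  if (isTRUE(cfg_get("regress", TRUE)) && is.null(res$inputs$phenotypes)) {
    abort("config error: regression requested but no phenotype table given")
  }
  ds <- stage("truncate", {
    truncate_wavelengths(res$inputs$spectra,
                         cfg_get("wl_lo", 1100), cfg_get("wl_hi", 1850))
  })
  holdout <- cfg_get("holdout_strains", character(0))
  model_ds <- ds[!ds$strain_id %in% holdout, ]
  holdout_ds <- ds[ds$strain_id %in% holdout, ]

  window <- config$window
  if (is.null(window)) {
    res$window_scan <- stage("scan-window", {
      scan_ds <- model_ds
      step <- cfg_get("scan_step_min", NULL)
      if (!is.null(step)) {
        keep <- (scan_ds$time_min - min(scan_ds$time_min)) %% step == 0
        scan_ds <- scan_ds[keep, ]
      }
      sc <- moving_window_pca(scan_ds, cfg_get("window_len", 10),
                              cfg_get("plane", c(2, 3)), pcfg)
      readr::write_csv(tidy(sc), file.path(config$out_dir, "window_scan.csv"))
      sc
    })
    window <- c(res$window_scan$selected$t_start,
                res$window_scan$selected$t_end)
  }
  logf("analysis window: %.0f-%.0f min", window[1], window[2])
  win_ds <- select_time_window(model_ds, window[1], window[2])

  res$classification <- stage("classify", {
    cv <- cross_validate_classifier(win_ds, cfg_get("n_predictive", NULL),
                                    cfg_get("n_orthogonal", 1), pcfg)
    readr::write_csv(cv$spectrum,
                     file.path(config$out_dir, "classification_spectra.csv"))
    readr::write_csv(cv$strain,
                     file.path(config$out_dir, "classification_strains.csv"))
    logf("one-strain-out accuracy: %.1f%% strains, %.1f%% spectra",
         cv$accuracy_strain, cv$accuracy_spectrum)
    cv
  })
  if (length(holdout) > 0) {
    res$independent <- stage("independent-validation", {
      iv <- independent_validation(
        win_ds, select_time_window(holdout_ds, window[1], window[2]),
        cfg_get("n_predictive", NULL), cfg_get("n_orthogonal", 1), pcfg)
      readr::write_csv(iv$fractions,
                       file.path(config$out_dir, "independent_validation.csv"))
      iv
    })
  }

  if (isTRUE(cfg_get("regress", TRUE))) {
    res$regression <- stage("regress", {
      ph <- res$inputs$phenotypes
      out <- lapply(c(bile_mic = "bile_mic", acid_yield = "acid_yield"),
                    function(v) {
        targets <- tibble::tibble(strain_id = ph$strain_id, value = ph[[v]])
        targets <- targets[targets$strain_id %in% win_ds$strain_id, ]
        cross_validate_regressor(win_ds, targets, cfg_get("n_lv", 2), pcfg)
      })
      metrics <- dplyr::bind_rows(lapply(out, function(r) r$metrics),
                                  .id = "target")
      readr::write_csv(metrics,
                       file.path(config$out_dir, "regression_metrics.csv"))
      out
    })
  }

  res$aquagram <- stage("aquagram", {
    sgmsc <- preprocess_fit_apply(
      win_ds, cfg = preprocess_cfg(sg_window = pcfg$sg_window,
                                   sg_order = pcfg$sg_order,
                                   scaling = "none"))
    prof <- compute_aquagram(sgmsc$train)
    readr::write_csv(prof, file.path(config$out_dir, "aquagram.csv"))
    prof
  })

  if (!is.null(res$inputs$phenotypes)) {
    res$probioticity <- stage("probioticity", {
      sc <- probioticity_scores(res$inputs$phenotypes)
      readr::write_csv(
        dplyr::mutate(sc, pc1_variance_pct = attr(sc, "pc1_variance_pct")),
        file.path(config$out_dir, "probioticity.csv"))
      sc
    })
  }
  logf("pipeline complete")
  invisible(res)
}
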