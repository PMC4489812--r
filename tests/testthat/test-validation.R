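test_that("one-strain-out folds partition the spectra by strain", {
  sim <- simulate_experiment(cfg_window(wl_step = 10))
  folds <- one_strain_out_split(sim$spectra)
  expect_length(folds, 15)
  expect_equal(vapply(folds, function(f) f$strain, ""),
               sort(unique(sim$spectra$strain_id)))
  test_rows <- dplyr::bind_rows(lapply(folds, function(f) f$test))
  expect_equal(nrow(test_rows), nrow(sim$spectra))
  expect_equal(sort(table(test_rows$strain_id)), sort(table(sim$spectra$strain_id)))
  for (f in folds[1:3]) {
    expect_false(f$strain %in% f$train$strain_id)
    expect_equal(unique(f$test$strain_id), f$strain)
  }
  one <- sim$spectra[sim$spectra$strain_id == "P01", ]
  expect_error(one_strain_out_split(one), ">= 2 strains")
})

test_that("held-out strains cannot influence a fold model", {
  sim <- simulate_experiment(cfg_window(wl_step = 10))
  ds <- sim$spectra
  corrupted <- ds
  idx <- corrupted$strain_id == "N01"
  corrupted[idx, -(1:3)] <- corrupted[idx, -(1:3)] * 10 + 3
  fold <- function(d) {
    f <- one_strain_out_split(d)[[6]]  # N01 held out
    pp <- preprocess_fit_apply(f$train, cfg = preprocess_cfg())
    fit_oplsda(spectra_matrix(pp$train), spectra_meta(pp$train)$group)
  }
  expect_equal(fold(ds), fold(nir_spectra(corrupted)))
})

test_that("classifier cross-validation separates planted groups and not shuffled ones", {
  sim <- simulate_experiment(cfg_window(seed = 1))
  rep <- suppressMessages(cross_validate_classifier(sim$spectra))
  expect_equal(rep$accuracy_strain, 100)
  expect_equal(sum(rep$confusion), nrow(sim$spectra))
  expect_equal(as.numeric(rowSums(rep$confusion)),
               as.numeric(table(sim$spectra$group)[rownames(rep$confusion)]))
  expect_true(all(glance(rep)[1, 1:2] >= 0 & glance(rep)[1, 1:2] <= 100))
  # strain-level calls come from majority votes over that strain's spectra
  expect_equal(nrow(rep$strain), 15)
  # single-group data is degenerate
  single <- sim$spectra[sim$spectra$group == "probiotic", ]
  expect_error(cross_validate_classifier(single), "degenerate")
  # shuffled labels: strain accuracy collapses towards chance
  null <- simulate_null_experiment(cfg_window(seed = 1))
  nrep <- suppressMessages(cross_validate_classifier(null$spectra))
  expect_lt(nrep$accuracy_strain, 60)
})

test_that("strain-level accuracy dominates spectrum-level accuracy under symmetric noise", {
  for (s in 1:3) {
    sim <- simulate_experiment(cfg_window(seed = s))
    rep <- suppressMessages(cross_validate_classifier(sim$spectra))
    expect_gte(rep$accuracy_strain, rep$accuracy_spectrum)
  }
})

test_that("regressor cross-validation recovers a noiseless planted link", {
  sim <- simulate_experiment(cfg_deterministic())
  ph <- sim$phenotypes
  res <- cross_validate_regressor(sim$spectra, strain_targets(ph, "bile_mic"),
                                  n_lv = 2,
                                  cfg = preprocess_cfg(apply_msc = FALSE))
  rng <- diff(range(ph$bile_mic))
  expect_lt(res$metrics$rmse[res$metrics$context == "cv"], 0.01 * rng)
  expect_equal(nrow(res$per_strain), 15)
  expect_named(res$per_strain, c("strain_id", "rmsep"))
  expect_error(
    cross_validate_regressor(sim$spectra,
                             tibble::tibble(strain_id = ph$strain_id, value = 1)),
    "constant")
  expect_error(
    cross_validate_regressor(sim$spectra,
                             strain_targets(ph, "bile_mic")[1:3, ]),
    "target missing")
})

test_that("independent validation reports per-strain assignment fractions", {
  sim <- simulate_experiment(cfg_window(wl_step = 5))
  ds <- sim$spectra
  train <- ds[!ds$strain_id %in% c("P01", "N01"), ]
  test <- ds[ds$strain_id %in% c("P01", "N01"), ]
  iv <- suppressMessages(independent_validation(train, test))
  expect_true(all(iv$fractions$pct > 0 & iv$fractions$pct <= 100))
  agg <- tapply(iv$fractions$pct, iv$fractions$strain_id, sum)
  expect_equal(as.numeric(agg), rep(100, 2))
  # archetypal new strains go fully to their own group
  p01 <- iv$fractions[iv$fractions$strain_id == "P01", ]
  expect_equal(p01$predicted[which.max(p01$pct)], "probiotic")
  # test = train subset is perfect
  sub <- ds[ds$strain_id %in% c("P02", "M02"), ]
  train2 <- ds[!ds$strain_id %in% c("P01", "N01"), ]
  iv2 <- suppressMessages(independent_validation(train2, sub))
  expect_equal(mean(iv2$assignments$predicted == iv2$assignments$group), 1)
  # empty test set gives an empty report
  iv0 <- suppressMessages(independent_validation(train, ds[0, ]))
  expect_equal(nrow(iv0$assignments), 0)
  expect_equal(nrow(iv0$fractions), 0)
})
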