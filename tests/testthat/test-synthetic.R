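test_that("logistic growth hits its anchors and its log-slope equals mu_max", {
  expect_equal(simulate_growth_curve(0.3, 0.1, 2.9, 0), 0.1)
  expect_equal(simulate_growth_curve(0.3, 0.1, 2.9, 1e7), 2.9, tolerance = 1e-6)
  # the log-slope ceiling is mu * (1 - od0/od_max); with a dilute inoculum
  # it matches mu_max to within 2% at the 4-min sampling cadence
  times <- seq(0, 2400, 4)
  od <- simulate_growth_curve(0.35, 0.02, 2.9, times)
  slope <- max(diff(log(od)) / diff(times / 60))
  expect_equal(slope, 0.35, tolerance = 0.02)
  expect_error(simulate_growth_curve(0.3, 0.5, 0.4, 0), "od_max > od0")
})

test_that("the spectrum generator is deterministic per seed", {
  arch <- default_archetypes()[1, ]
  cfg <- sim_config(wl_step = 5)
  s1 <- simulate_spectrum(arch, od = 1.2, t_min = 600, cfg, seed = 99)
  s2 <- simulate_spectrum(arch, od = 1.2, t_min = 600, cfg, seed = 99)
  expect_identical(s1, s2)
  expect_length(s1, length(seq(1100, 1850, 5)))
  sim1 <- simulate_experiment(cfg_window(wl_step = 10))
  sim2 <- simulate_experiment(cfg_window(wl_step = 10))
  expect_identical(sim1$spectra, sim2$spectra)
  expect_identical(sim1$phenotypes, sim2$phenotypes)
  sim3 <- simulate_experiment(cfg_window(wl_step = 10, seed = 2))
  expect_false(identical(sim1$spectra, sim3$spectra))
})

test_that("od coupling off makes spectra independent of optical density", {
  arch <- default_archetypes()[2, ]
  cfg <- sim_config(wl_step = 5, od_coupling = 0, noise_sd = 0,
                    scatter = FALSE, drift = FALSE, envelope = "none")
  a <- simulate_spectrum(arch, od = 0.2, t_min = 100, cfg)
  b <- simulate_spectrum(arch, od = 2.2, t_min = 900, cfg)
  expect_equal(a, b)
  cfg2 <- sim_config(wl_step = 5, noise_sd = 0, scatter = FALSE,
                     drift = FALSE, envelope = "none")
  expect_false(isTRUE(all.equal(simulate_spectrum(arch, 0.2, 100, cfg2),
                                simulate_spectrum(arch, 2.2, 900, cfg2))))
})

test_that("MSC recovers the scatter-free spectra of a common-shape strain block", {
  base <- sim_config(wl_step = 2, scans_per_strain = 30, cadence_min = 4,
                     noise_sd = 0, drift = FALSE, od_coupling = 0,
                     envelope = "none", trait_jitter_sd = 0,
                     mu_jitter_frac = 0, od_max_jitter_frac = 0,
                     od0_jitter_frac = 0, phenotype_noise_frac = 0, seed = 5)
  on <- base
  off <- base
  off$scatter <- FALSE
  ds_on <- simulate_experiment(on)$spectra
  ds_off <- simulate_experiment(off)$spectra
  idx <- ds_on$group == "probiotic"  # one group = one common shape
  x_on <- spectra_matrix(ds_on)[idx, ]
  x_off <- spectra_matrix(ds_off)[idx, ]
  # correcting against the scatter-free reference inverts the planted
  # per-scan gains and offsets exactly
  corrected <- apply_msc(x_on, fit_msc(x_off))
  expect_lt(sqrt(mean((corrected - x_off)^2)), 1e-8)
  # self-referenced correction collapses all scans onto one common shape
  self_corr <- apply_msc(x_on, fit_msc(x_on))
  expect_lt(max(apply(self_corr, 2, sd)), 1e-8)
})

test_that("the default experiment has the instrument shape: 15 x 300 = 4500 spectra", {
  sim <- simulate_experiment(sim_config(wl_step = 10))
  expect_equal(nrow(sim$spectra), 4500)
  expect_equal(length(unique(sim$spectra$strain_id)), 15)
  expect_equal(as.numeric(table(sim$spectra$group)), rep(1500, 3))
  expect_equal(min(sim$spectra$time_min), 40)
  expect_equal(sort(unique(diff(sort(unique(sim$spectra$time_min))))), 4)
  expect_equal(nrow(sim$phenotypes), 15)
  # phenotypes follow the planted affine links up to the configured noise
  links <- sim$truth$phenotype_links
  g <- sim$truth$strains
  exact <- links$bile_mic["intercept"] + links$bile_mic["g1365"] * g$g1365
  expect_equal(sim$truth$phenotypes_exact$bile_mic, unname(exact))
  expect_lt(max(abs(sim$phenotypes$bile_mic - exact)),
            5 * 0.02 * diff(range(exact)) + 1e-9)
})

test_that("clean group archetypes separate on non-drift components", {
  cfg <- cfg_window(noise_sd = 0, scatter = FALSE, wl_step = 5)
  sim <- simulate_experiment(cfg)
  pp <- preprocess_fit_apply(sim$spectra)
  pca <- fit_pca(spectra_matrix(pp$train), 3)
  r <- separation_ratio(pca$scores[, c(2, 3)], sim$spectra$group)
  expect_gt(min(r$ratio), 1)
})

test_that("the planted separation proxy peaks inside the monitored span", {
  cfg <- cfg_scan()
  proxy <- planted_separation_proxy(cfg)
  expect_equal(nrow(proxy), cfg$scans_per_strain)
  expect_true(all(proxy$min_ratio >= 0))
  pk <- planted_peak_window(proxy)
  expect_gt(pk[1], min(proxy$time_min))
  expect_lt(pk[2], max(proxy$time_min))
  # the peak is an interior maximum: ends of the run are clearly lower
  expect_lt(proxy$min_ratio[1], 0.75 * max(proxy$min_ratio))
  expect_lt(proxy$min_ratio[nrow(proxy)], 0.75 * max(proxy$min_ratio))
})
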