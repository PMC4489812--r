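# Shared fixtures: all synthetic, built in code at test time.

# Small hand-built spectral tibble: n scans per strain on a uniform grid.
toy_spectra <- function(n_strains = 2, scans = 3, wl = seq(1100, 1104, 0.5),
                        groups = rep("probiotic", n_strains), seed = 42) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_strains), function(i) {
      a <- matrix(runif(scans * length(wl), 0.2, 0.8), scans)
      dplyr::bind_cols(
        tibble::tibble(strain_id = sprintf("S%02d", i), group = groups[i],
                       time_min = 40 + 4 * (seq_len(scans) - 1)),
        tibble::as_tibble(`colnames<-`(a, as.character(wl))))
    })
    nir_spectra(dplyr::bind_rows(rows))
  })
}

# Reduced-size simulation configs used throughout the suite. Same generative
# amplitudes as the defaults; only grid, cadence and scan counts are scaled
# down so the suite stays fast.
cfg_window <- function(seed = 1, wl_step = 2, ...) {
  sim_config(wl_step = wl_step, scans_per_strain = 10, cadence_min = 4,
             t_start_min = 520, seed = seed, ...)
}

cfg_scan <- function(seed = 1, ...) {
  sim_config(wl_step = 5, scans_per_strain = 80, cadence_min = 15,
             seed = seed, ...)
}

# Deterministic generator mode: every stochastic and time-varying term off,
# X exactly linear in the planted trait gains.
cfg_deterministic <- function(seed = 1) {
  sim_config(wl_step = 2, scans_per_strain = 10, cadence_min = 4,
             t_start_min = 520, seed = seed, noise_sd = 0,
             phenotype_noise_frac = 0, drift = FALSE, scatter = FALSE,
             envelope = "none", od_coupling = 0, sep_amplitude = 0)
}

strain_targets <- function(ph, var) {
  tibble::tibble(strain_id = ph$strain_id, value = ph[[var]])
}

# Brute-force per-point Savitzky-Golay oracle: explicit local polynomial
# least squares at each channel, truncating the window at the edges.
savgol_oracle <- function(y, window, order) {
  p <- length(y)
  half <- (window - 1) / 2
  sapply(seq_len(p), function(i) {
    idx <- max(1, i - half):min(p, i + half)
    fit <- lm.fit(outer(idx - i, 0:order, "^"), y[idx])
    unname(fit$coefficients[1])
  })
}
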