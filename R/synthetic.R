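#' Simulation configuration
#'
#' Defines an instrument-shaped in-silico growth-monitoring experiment:
#' 3 strain groups x `n_per_group` strains, `scans_per_strain` transflectance
#' scans at a fixed cadence starting 40 min after inoculation, on a uniform
#' wavelength grid. The signal model per scan is a sum of Gaussian absorbance
#' bands of the first overtone of water whose amplitudes carry (i) a common
#' growth-linked term proportional to culture optical density, (ii)
#' group-specific offsets scaled by the growth envelope `OD(t)/OD_max` so the
#' group separation develops towards late exponential phase, and (iii) static
#' strain trait gains on the 1365 and 1485 nm bands that the phenotype table
#' is affinely linked to; plus a slow two-shape "temperature" drift whose
#' amplitude ramps up late in the run, i.i.d. Gaussian noise, and per-scan
#' multiplicative scatter.
#'
#' @param n_per_group Strains per group (default 5).
#' @param scans_per_strain Scans per strain (default 300).
#' @param cadence_min Minutes between scans (default 4).
#' @param t_start_min Time of the first retained scan (default 40).
#' @param wl_lo,wl_hi,wl_step Wavelength grid in nm (default 1100-1850 at
#'   0.5 nm).
#' @param noise_sd Additive spectral noise SD in absorbance (default 1e-3).
#' @param phenotype_noise_frac Phenotype noise as a fraction of each
#'   variable's range (default 0.02).
#' @param scatter Logical; apply per-scan multiplicative scatter.
#' @param scatter_gain,scatter_offset Uniform ranges for the per-scan gain
#'   and offset.
#' @param drift Logical; apply the slow temperature drift.
#' @param drift_amplitude Drift coefficient amplitude (absorbance).
#' @param drift_d2_frac Relative amplitude of the secondary drift shape.
#' @param drift_ramp_gain,drift_ramp_time_min,drift_ramp_tau_min Late-run
#'   drift instability: amplitude multiplier `1 + gain * sigmoid((t - t0)/tau)`.
#' @param sep_amplitude Amplitude of the group-specific band offsets
#'   (absorbance at band centre; default 5e-3 = 5 x `noise_sd`).
#' @param envelope `"od"` scales group offsets by `OD(t)/OD_max`; `"none"`
#'   keeps them constant (deterministic mode used for algebraic checks).
#' @param od_coupling Multiplier on the od-linked band term (0 disables it).
#' @param trait_jitter_sd SD of the per-strain trait-gain jitter.
#' @param mu_jitter_frac,od_max_jitter_frac Relative SD of per-strain growth
#'   parameter jitter.
#' @param od0_jitter_frac Relative SD of the inoculation density jitter
#'   (desynchronizes early growth; forgotten once cultures saturate).
#' @param seed Integer seed fixing the whole stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 5, scans_per_strain = 300,
                       cadence_min = 4, t_start_min = 40,
                       wl_lo = 1100, wl_hi = 1850, wl_step = 0.5,
                       noise_sd = 1e-3, phenotype_noise_frac = 0.02,
                       scatter = TRUE,
                       scatter_gain = c(0.9, 1.1),
                       scatter_offset = c(-0.02, 0.02),
                       drift = TRUE, drift_amplitude = 0.035,
                       drift_d2_frac = 0.06,
                       drift_ramp_gain = 8, drift_ramp_time_min = 780,
                       drift_ramp_tau_min = 50,
                       sep_amplitude = 5e-3,
                       envelope = c("od", "none"),
                       od_coupling = 1,
                       trait_jitter_sd = 5e-4,
                       mu_jitter_frac = 0.01, od_max_jitter_frac = 0.01,
                       od0_jitter_frac = 0,
                       seed = 1) {
  envelope <- match.arg(envelope)
  cfg <- as.list(environment())
  stopifnot(n_per_group >= 1, scans_per_strain >= 1, cadence_min > 0,
            wl_lo < wl_hi, wl_step > 0)
  structure(cfg, class = "sim_config")
}

#' Group archetypes for the simulated strains
#'
#' Growth parameters per group are the group means of the reference
#' phenotype table ([lactobacillus_phenotypes()]): probiotic strains grow
#' fastest to the highest density, non-probiotic slowest to the lowest.
#' `g1365` / `g1485` are the static trait-band gains the phenotypes are
#' linked to: the 1365 nm gain (probiotic-elevated) drives bile tolerance
#' and acid-stress yield, the 1485 nm gain is moderate-elevated.
#'
#' @return A tibble with one row per group.
#' @export
default_archetypes <- function() {
  tibble::tribble(
    ~group,          ~mu_max, ~od0, ~od_max, ~g1365, ~g1485,
    "probiotic",       0.350,  0.1,   2.913,  0.060,  0.045,
    "moderate",        0.280,  0.1,   2.257,  0.050,  0.065,
    "non_probiotic",   0.220,  0.1,   1.301,  0.040,  0.045
  )
}

# Gaussian band table of the simulated first water overtone. `gamma` is the
# od-independent baseline amplitude, `beta` the od-linked slope, the three
# off_* columns the unit group offsets (multiplied by cfg$sep_amplitude and
# the growth envelope), `trait` names the static strain-gain carried by the
# band. Probiotic offsets sit on 1374-1426 (with non-probiotic depressed),
# moderate offsets on 1476-1486.
sim_bands <- function() {
  tibble::tribble(
    ~center, ~width, ~gamma,  ~beta, ~off_probiotic, ~off_moderate, ~off_non_probiotic, ~trait,
    1155,     25,     0.15,  0.004,  0,  0,    0,  NA,
    1342,     10,     0.05,  0.006,  0,  0,    0,  NA,
    1364,     12,     0.06,  0.024,  0,  0,    0,  NA,
    1365,     14,     0.00,  0.000,  0,  0,    0,  "g1365",
    1374,     10,     0.05,  0.008,  0,  0,    0,  NA,
    1384,     10,     0.05,  0.008,  0,  0,    0,  NA,
    1408,     30,     0.50,  0.006,  0,  0,    0,  NA,
    1412,     10,     0.05,  0.008,  1,  0, -0.6,  NA,
    1426,     10,     0.05,  0.008,  1,  0, -0.6,  NA,
    1440,     12,     0.06,  0.010,  0,  0,    0,  NA,
    1450,     45,     1.00, -0.008,  0,  0,    0,  NA,
    1452,     12,     0.06,  0.010,  0,  0,    0,  NA,
    1462,     10,     0.05,  0.008,  0,  0,    0,  NA,
    1476,     10,     0.05,  0.008,  0,  1,    0,  NA,
    1485,     12,     0.00,  0.000,  0,  0,    0,  "g1485",
    1486,     10,     0.05,  0.008,  0,  1,    0,  NA
  )
}

# Affine links from the static trait gains to the wet-lab phenotypes.
sim_phenotype_links <- function() {
  list(bile_mic = c(intercept = -3.7, g1365 = 100, g1485 = 0),
       acid_yield = c(intercept = -0.21, g1365 = 5.6, g1485 = 0.2))
}

#' Logistic growth curve
#'
#' Verhulst growth of culture optical density:
#' `OD(t) = od_max * od0 * exp(mu t) / (od_max - od0 + od0 * exp(mu t))`,
#' `t` in hours. The maximal slope of `ln OD` equals `mu_max`.
#'
#' @param mu_max Maximal specific growth rate (1/h).
#' @param od0 Inoculation optical density.
#' @param od_max Carrying capacity (maximal OD).
#' @param times_min Sampling times in minutes.
#' @return Numeric OD series.
#' @export
simulate_growth_curve <- function(mu_max, od0, od_max, times_min) {
  stopifnot(od_max > od0, od0 > 0, mu_max > 0)
  t_h <- times_min / 60
  od_max / (1 + (od_max - od0) / od0 * exp(-mu_max * t_h))
}

# Gaussian band shapes on the wavelength grid: channels x bands.
sim_band_shapes <- function(wl, bands = sim_bands()) {
  B <- vapply(seq_len(nrow(bands)), function(k) {
    exp(-0.5 * ((wl - bands$center[k]) / bands$width[k])^2)
  }, numeric(length(wl)))
  dimnames(B) <- list(NULL, paste0("b", bands$center))
  B
}

# Two fixed drift shapes: the dominant "temperature" shape D1 (water band
# shifting) and a secondary shape D2 placed away from the discriminative
# bands so it perturbs the score plane without mimicking group structure.
sim_drift_shapes <- function(wl) {
  d1 <- exp(-0.5 * ((wl - 1412) / 35)^2) - exp(-0.5 * ((wl - 1470) / 40)^2)
  d2 <- exp(-0.5 * ((wl - 1310) / 20)^2) - exp(-0.5 * ((wl - 1550) / 30)^2)
  cbind(d1 = d1 / max(abs(d1)), d2 = d2 / max(abs(d2)))
}

sim_ramp <- function(t_min, cfg) {
  1 + cfg$drift_ramp_gain /
    (1 + exp(-(t_min - cfg$drift_ramp_time_min) / cfg$drift_ramp_tau_min))
}

sim_wavelengths <- function(cfg) {
  seq(cfg$wl_lo, cfg$wl_hi, by = cfg$wl_step)
}

sim_times <- function(cfg) {
  cfg$t_start_min + cfg$cadence_min * (seq_len(cfg$scans_per_strain) - 1)
}

# Deterministic band-amplitude matrix (scans x bands) of one strain.
sim_band_amplitudes <- function(od, group, gains, cfg, bands = sim_bands()) {
  env <- if (cfg$envelope == "od") od / gains$od_max_used else
    rep(1, length(od))
  n <- length(od)
  amp <- matrix(0, n, nrow(bands))
  offcol <- paste0("off_", group)
  for (k in seq_len(nrow(bands))) {
    a <- bands$gamma[k] + cfg$od_coupling * bands$beta[k] * od +
      cfg$sep_amplitude * bands[[offcol]][k] * env
    if (!is.na(bands$trait[k])) a <- a + gains[[bands$trait[k]]]
    amp[, k] <- a
  }
  amp
}

#' Simulate a single spectrum
#'
#' Builds one transflectance absorbance spectrum of a culture of the given
#' archetype at optical density `od` and cultivation time `t_min`, under the
#' configured band model, drift, noise and scatter. Randomness (noise,
#' scatter, drift phase) is drawn from R's RNG; pass `seed` to make the call
#' reproducible in isolation.
#'
#' @param arch One row of [default_archetypes()] (list or one-row tibble).
#' @param od Optical density of the culture at the scan.
#' @param t_min Cultivation time in minutes.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A named numeric vector (one absorbance per channel).
#' @export
simulate_spectrum <- function(arch, od, t_min, cfg = sim_config(),
                              seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  arch <- as.list(arch)
  wl <- sim_wavelengths(cfg)
  bands <- sim_bands()
  B <- sim_band_shapes(wl, bands)
  gains <- list(g1365 = arch$g1365, g1485 = arch$g1485,
                od_max_used = arch$od_max)
  amp <- sim_band_amplitudes(od, arch$group, gains, cfg, bands)
  x <- drop(amp %*% t(B))
  if (cfg$drift) {
    D <- sim_drift_shapes(wl)
    ph <- runif(2, 0, 2 * pi)
    r <- sim_ramp(t_min, cfg)
    c1 <- cfg$drift_amplitude * r * sin(2 * pi * (t_min - 40) / 120 + ph[1])
    c2 <- cfg$drift_amplitude * cfg$drift_d2_frac * r *
      sin(2 * pi * (t_min - 40) / 80 + ph[2])
    x <- x + c1 * D[, 1] + c2 * D[, 2]
  }
  x <- x + rnorm(length(wl), 0, cfg$noise_sd)
  if (cfg$scatter) {
    g <- runif(1, cfg$scatter_gain[1], cfg$scatter_gain[2])
    o <- runif(1, cfg$scatter_offset[1], cfg$scatter_offset[2])
    x <- o + g * x
  }
  setNames(x, as.character(wl))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) return(invisible())
  assign(".Random.seed", state, envir = globalenv())
}

#' Simulate a full growth-monitoring experiment
#'
#' Emits 3 groups x `n_per_group` strains x `scans_per_strain` spectra on the
#' standard cadence plus a matching phenotype table whose bile MIC and
#' acid-stress yield are affine functions of the planted 1365/1485 trait
#' gains (plus noise), so PLS regression recovery is well-posed. The full
#' random stream is fixed by `cfg$seed`. The generative ground truth (strain
#' parameters, band table, phenotype link coefficients, and the planted
#' separation-versus-time proxy with its peak window) is returned as the
#' `truth` element so recovery tests are self-auditing.
#'
#' @param cfg A [sim_config()].
#' @param archetypes Group archetype table ([default_archetypes()]).
#' @return A list of class `nir_simulation` with elements `spectra`
#'   (a `nir_spectra` tibble), `phenotypes` and `truth`.
#' @export
simulate_experiment <- function(cfg = sim_config(),
                                archetypes = default_archetypes()) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(cfg$seed)
  wl <- sim_wavelengths(cfg)
  times <- sim_times(cfg)
  bands <- sim_bands()
  B <- sim_band_shapes(wl, bands)
  D <- sim_drift_shapes(wl)
  prefix <- c(probiotic = "P", moderate = "M", non_probiotic = "N")
  strains <- purrr::map_dfr(seq_len(nrow(archetypes)), function(gi) {
    a <- archetypes[gi, ]
    tibble::tibble(
      strain_id = sprintf("%s%02d", prefix[[a$group]], seq_len(cfg$n_per_group)),
      group = a$group,
      mu_max = a$mu_max * (1 + rnorm(cfg$n_per_group, 0, cfg$mu_jitter_frac)),
      od0 = a$od0 * (1 + rnorm(cfg$n_per_group, 0, cfg$od0_jitter_frac)),
      od_max = a$od_max * (1 + rnorm(cfg$n_per_group, 0, cfg$od_max_jitter_frac)),
      g1365 = a$g1365 + rnorm(cfg$n_per_group, 0, cfg$trait_jitter_sd),
      g1485 = a$g1485 + rnorm(cfg$n_per_group, 0, cfg$trait_jitter_sd),
      drift_phase1 = runif(cfg$n_per_group, 0, 2 * pi),
      drift_phase2 = runif(cfg$n_per_group, 0, 2 * pi),
      drift_period1 = rnorm(cfg$n_per_group, 120, 10),
      drift_period2 = rnorm(cfg$n_per_group, 80, 8))
  })
  blocks <- vector("list", nrow(strains))
  for (i in seq_len(nrow(strains))) {
    s <- strains[i, ]
    od <- simulate_growth_curve(s$mu_max, s$od0, s$od_max, times)
    gains <- list(g1365 = s$g1365, g1485 = s$g1485, od_max_used = s$od_max)
    amp <- sim_band_amplitudes(od, s$group, gains, cfg, bands)
    x <- amp %*% t(B)
    if (cfg$drift) {
      r <- sim_ramp(times, cfg)
      c1 <- cfg$drift_amplitude * r *
        sin(2 * pi * (times - 40) / s$drift_period1 + s$drift_phase1)
      c2 <- cfg$drift_amplitude * cfg$drift_d2_frac * r *
        sin(2 * pi * (times - 40) / s$drift_period2 + s$drift_phase2)
      x <- x + tcrossprod(c1, D[, 1]) + tcrossprod(c2, D[, 2])
    }
    x <- x + matrix(rnorm(length(x), 0, cfg$noise_sd), nrow(x))
    if (cfg$scatter) {
      g <- runif(nrow(x), cfg$scatter_gain[1], cfg$scatter_gain[2])
      o <- runif(nrow(x), cfg$scatter_offset[1], cfg$scatter_offset[2])
      x <- o + g * x
    }
    blocks[[i]] <- dplyr::bind_cols(
      tibble::tibble(strain_id = s$strain_id, group = s$group,
                     time_min = times),
      tibble::as_tibble(`colnames<-`(x, as.character(wl))))
  }
  spectra <- nir_spectra(dplyr::bind_rows(blocks))
  links <- sim_phenotype_links()
  ph_exact <- tibble::tibble(
    strain_id = strains$strain_id, group = strains$group,
    mu_max = strains$mu_max, od_max = strains$od_max,
    bile_mic = links$bile_mic["intercept"] +
      links$bile_mic["g1365"] * strains$g1365 +
      links$bile_mic["g1485"] * strains$g1485,
    acid_yield = links$acid_yield["intercept"] +
      links$acid_yield["g1365"] * strains$g1365 +
      links$acid_yield["g1485"] * strains$g1485)
  noisy <- function(v) {
    pmax(0, v + rnorm(length(v), 0, cfg$phenotype_noise_frac * diff(range(v))))
  }
  phenotypes <- ph_exact
  if (cfg$phenotype_noise_frac > 0) {
    phenotypes$bile_mic <- noisy(ph_exact$bile_mic)
    phenotypes$acid_yield <- noisy(ph_exact$acid_yield)
  }
  truth <- list(config = cfg, archetypes = archetypes, strains = strains,
                bands = bands, phenotype_links = links,
                phenotypes_exact = ph_exact)
  truth$separation_proxy <- planted_separation_proxy(cfg, archetypes)
  truth$peak_window <- planted_peak_window(truth$separation_proxy)
  structure(list(spectra = spectra, phenotypes = validate_phenotypes(phenotypes),
                 truth = truth),
            class = "nir_simulation")
}

#' @export
print.nir_simulation <- function(x, ...) {
  cat(sprintf(
    "<nir_simulation> %d strains x %d scans, %d channels; planted peak %.0f-%.0f min\n",
    length(unique(x$spectra$strain_id)),
    x$truth$config$scans_per_strain, length(wavelengths(x$spectra)),
    x$truth$peak_window[1], x$truth$peak_window[2]))
  invisible(x)
}

#' Deterministic separation-versus-time proxy of a configuration
#'
#' Computes, from the archetype growth curves and the configured amplitudes
#' only (no random draws), the expected pairwise group-separation ratio over
#' cultivation time: the numerator is the Euclidean distance between the
#' deterministic group-centre spectra, the denominator the sum of the two
#' groups' within-group spread components (additive noise, trait-gain
#' jitter, and the secondary drift shape whose amplitude follows the late
#' ramp). This is the generator's own account of where the planted group
#' separation peaks; its argmax region defines the planted peak window.
#'
#' @param cfg A [sim_config()].
#' @param archetypes Group archetype table.
#' @return A tibble with `time_min`, pairwise proxy ratios and `min_ratio`.
#' @export
planted_separation_proxy <- function(cfg, archetypes = default_archetypes()) {
  wl <- sim_wavelengths(cfg)
  times <- sim_times(cfg)
  bands <- sim_bands()
  B <- sim_band_shapes(wl, bands)
  D <- sim_drift_shapes(wl)
  centres <- lapply(seq_len(nrow(archetypes)), function(gi) {
    a <- archetypes[gi, ]
    od <- simulate_growth_curve(a$mu_max, a$od0, a$od_max, times)
    gains <- list(g1365 = a$g1365, g1485 = a$g1485, od_max_used = a$od_max)
    sim_band_amplitudes(od, a$group, gains, cfg, bands) %*% t(B)
  })
  jit <- cfg$trait_jitter_sd *
    sqrt(sum(B[, bands$trait %in% "g1365"]^2) +
           sum(B[, bands$trait %in% "g1485"]^2))
  d2_norm <- sqrt(sum(D[, 2]^2))
  d2_spread <- if (cfg$drift) {
    cfg$drift_amplitude * cfg$drift_d2_frac * sim_ramp(times, cfg) *
      d2_norm / sqrt(2)
  } else rep(0, length(times))
  noise <- cfg$noise_sd * sqrt(2)
  spread <- sqrt(noise^2 + jit^2 + d2_spread^2)
  pairs <- utils::combn(nrow(archetypes), 2)
  out <- tibble::tibble(time_min = times)
  ratio_cols <- character(0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dist <- sqrt(rowSums((centres[[i]] - centres[[j]])^2))
    nm <- paste0("ratio_", archetypes$group[i], "_", archetypes$group[j])
    out[[nm]] <- dist / (2 * spread)
    ratio_cols <- c(ratio_cols, nm)
  }
  out$min_ratio <- do.call(pmin, out[ratio_cols])
  out
}

#' Planted peak window of a separation proxy
#'
#' @param proxy Output of [planted_separation_proxy()].
#' @param frac Fraction of the maximum defining the peak region (default
#'   0.9).
#' @return `c(t_lo, t_hi)` in minutes.
#' @export
planted_peak_window <- function(proxy, frac = 0.9) {
  peak <- proxy$time_min[proxy$min_ratio >= frac * max(proxy$min_ratio)]
  c(min(peak), max(peak))
}

#' Simulate a null experiment with no group structure
#'
#' All three groups share one archetype (growth and trait gains), and the
#' group-specific band offsets are zeroed, so class labels carry no signal;
#' used for permutation-style null checks of the classifier.
#'
#' @param cfg A [sim_config()].
#' @return A `nir_simulation` (see [simulate_experiment()]).
#' @export
simulate_null_experiment <- function(cfg = sim_config()) {
  cfg$sep_amplitude <- 0
  arch <- default_archetypes()
  arch$mu_max <- mean(arch$mu_max)
  arch$od_max <- mean(arch$od_max)
  arch$g1365 <- mean(arch$g1365)
  arch$g1485 <- mean(arch$g1485)
  simulate_experiment(cfg, arch)
}
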