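---
title: "Methods: aquaphotomic screening of probiotic strains from NIR growth spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aquaphotomic screening of probiotic strains from NIR growth spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the model

A growing *Lactobacillus* culture is monitored with a transflectance NIR
probe: one absorbance spectrum (log 1/T) every 4 minutes from 40 min to
about 20 h, on a 0.5 nm grid. Analysis is restricted to 1100–1850 nm, the
region containing the first overtone of water (1300–1600 nm). The working
hypothesis of aquaphotomics is that the water spectrum of the culture
medium — the pattern of absorbance at characteristic water matrix
coordinates (WAMACs) reflecting protonated clusters, hydration shells,
free and bound water — integrates the metabolic state of the cell
population, so strains with different stress resistance phenotypes leave
different water-spectral fingerprints while they grow.

The pipeline makes four inferential moves:

1. **When to look.** Group differences are transient: small early (too few
   cells) and degraded late (the culture is past stationary phase and the
   measurement drifts). Moving-window PCA slides a 10-scan window along the
   time course; in each window the pooled spectra of all strains are
   preprocessed, decomposed, and scored by the worst pairwise
   group-separation ratio on the (PC2, PC3) plane. The window maximizing
   that minimum is the analysis window.
2. **Who is who.** OPLS-DA on the analysis window classifies the three
   phenotype groups (probiotic / moderate / non-probiotic), validated
   one-strain-out so the claim is about *new strains*, not new scans.
3. **How strong.** PLS1 regression predicts the two quantitative stress
   phenotypes (bile MIC in mg/ml, acid/pepsin biomass yield in ΔOD665)
   from the window spectra, with the latent-variable count capped at
   one-tenth of the observations.
4. **One number per strain.** PCA on the four autoscaled wet-lab variables
   condenses probiotic strength into the PC1 score ("probioticity"),
   signed to correlate positively with bile tolerance.

## Preprocessing

The fixed chain is Savitzky–Golay → MSC → Pareto, implemented as a
fit/apply pair: reference spectrum and scaling statistics are estimated on
training spectra only and frozen before held-out strains are transformed.

* **Savitzky–Golay** (window 21 points = 10.5 nm on the instrument grid,
  polynomial order 2) removes channel noise without distorting band shapes
  that are wide relative to the window. Edges are handled by fitting the
  local polynomial on the truncated one-sided window rather than by
  padding, so no absorbance is fabricated beyond the measured range.
* **MSC** regresses each spectrum on the training-mean reference over
  channels (`x ≈ a + b·r`) and returns `(x − a)/b`. It exactly inverts
  affine distortions of the reference shape; for spectra that differ from
  the reference it is a first-order correction whose residual grows with
  the deviation (visible in the generator's deterministic checks, where
  MSC is skipped when no scatter is simulated).
* **Pareto scaling** divides centered channels by the square root of their
  training standard deviation: strong bands stay dominant but do not
  drown minor ones; channels with SD below 1e−12 map to 0 so flat
  synthetic channels cannot produce NaNs.

## Latent-variable engines

PCA is a mean-centered SVD; explained variance is reported for every
possible component and sums to 100 over the full rank. Component signs
follow the convention that each loading's largest-magnitude element is
positive, making score plots reproducible run to run.

PLS1 uses NIPALS: weights `w ∝ Xᵀy`, scores `t = Xw`, deflation of both
blocks, regression vector `B = W(PᵀW)⁻¹q`. With a single response the
inner iteration is closed-form, so fits are deterministic. The LV cap
`⌊n/10⌋` is enforced at fit time; `enforce_lv_cap = FALSE` exists only for
small algebraic checks (e.g. full-rank equivalence with least squares,
which the cap would otherwise forbid at n = 8).

OPLS-DA centers a one-hot class matrix, computes the predictive weight
space from the singular vectors of `XᵀY`, and per orthogonal component
orthogonalizes the dominant loading against that whole space:
`w_orth ∝ p − W(WᵀW)⁻¹Wᵀp`. Orthogonalizing against the full space (not
just the first weight) makes the orthogonal scores *exactly* uncorrelated
with every class column, which the tests assert at 1e−8. The filtered
matrix then gets a PLS2 discriminant model with `classes − 1 = 2`
predictive components (the two discriminant functions of the three-group
problem) and, by default, 1 orthogonal component — enough to absorb the
dominant drift direction. Class assignment is the argmax of the predicted
class memberships; ties break to the first class in sort order with a
warning. NIPALS for PLS2 iterates to a relative score tolerance of 1e−10
(max 500 iterations, warning on non-convergence).

## The separation ratio and the window convention

For groups i, j with centres `c_i, c_j` in the score plane and spreads
`s_g` = RMS Euclidean distance to the group centre, the ratio is
`‖c_i − c_j‖ / (s_i + s_j)` — invariant to rotation, translation and
uniform scaling of the plane. "Spread" is deliberately the RMS radius (not
per-axis SD), and the denominator the *sum* of the two spreads: the ratio
then reads as centre distance in units of the two clouds' combined size.
The optimal window maximizes the minimum over the three pairs, which
encodes "every pair separated at once"; ties pick the earliest window with
a message.

A course of N aligned scans and a w-scan window yields N − w windows
(starts 0 … N − w − 1): with N = 300 and w = 10, exactly 290 PCA models.
The plane defaults to (PC2, PC3) because PC1 of any single window is
dominated by the slow temperature drift of the water band; it is an
argument, not a constant.

## The synthetic experiment generator

`simulate_experiment()` is a first-class module, not a test stub. Per scan
the absorbance is a sum of Gaussian bands of the first water overtone plus
structured nuisance:

* **Common growth chemistry**: each band amplitude is `γ_k + β_k·OD(t)`,
  with OD following a logistic (Verhulst) curve
  `OD(t) = K / (1 + ((K − OD₀)/OD₀)e^{−μt}`. Group archetypes reach
  different carrying capacities (2.91 / 2.26 / 1.30, the group means of the
  reference phenotype table) with growth rates 0.35 / 0.28 / 0.22 h⁻¹,
  chosen so all groups pass late-exponential inside the 20 h run — the
  regime the study design depends on. Per-strain jitter of μ and K is 1%
  (replicate cultivations in a controlled medium are highly reproducible,
  and the one-tenth-LV-capped regressions are entitled to a stable
  growth stage).
* **Group-specific offsets** on the 1412/1426 nm bands
  (probiotic-elevated, non-probiotic-depressed) and 1476/1486 nm
  (moderate-elevated), with amplitude 5e−3 AU = 5 × the noise SD, scaled
  by the growth envelope `OD(t)/OD_max` so separation develops toward late
  exponential phase.
* **Static trait gains** on narrow 1365 and 1485 nm bands: per-strain
  quantities `g1365`, `g1485` that the phenotype table is affinely linked
  to (`bile MIC = −3.7 + 100·g1365`;
  `acid yield = −0.21 + 5.6·g1365 + 0.2·g1485`, plus 2%-of-range noise).
  The 1485 gain is elevated in the moderate group but symmetric between
  the probiotic and non-probiotic groups, so it carries aquagram contrast
  without covarying with bile MIC across groups — if it did, a 2-LV
  regression provably biases the middle group.
* **Temperature drift**: two fixed spectral shapes. D1 (a
  difference-of-Gaussians around 1412/1470 nm, the water band shifting
  with temperature) dominates within-window variance — amplitude 0.025 AU,
  25 × noise — and is what makes PC1 "the temperature component". Its
  amplitude must stay above the od-separation direction at all times,
  otherwise the separation itself takes PC1 and leaves the (PC2, PC3)
  plane; this coupling fixed the drift amplitude. Drift oscillates with
  ~120/80 min periods (thermostat cycling), so within a 36-min analysis
  window it partially averages out per strain instead of acting as a
  frozen per-strain bias. A second, weaker shape D2 sits away from the
  discriminative bands and its amplitude ramps up ~8× after 13 h
  (sigmoid, τ = 50 min): the late-run instability that ends the usable
  monitoring window and gives the separation ratio its interior peak.
* **Scatter and noise**: per-scan affine distortion with gain U(0.9, 1.1)
  and offset U(−0.02, 0.02); i.i.d. Gaussian channel noise, SD 1e−3 AU;
  phenotype noise 2% of each variable's range.

The generator records its ground truth (strain parameters, band table,
link coefficients) and a *deterministic separation proxy*: the expected
pairwise centre distances from the archetype curves divided by the
modelled spread components (noise, trait jitter, ramped D2). The proxy's
≥ 90%-of-max region defines the planted peak window that window-scan
recovery is tested against.

What the generator does **not** emulate: instrument line-shape and
detector nonlinearity, wavelength-calibration error, baseline steps,
medium batch effects, biological time-varying band shifts, or any
dependence structure in the noise. Passing tests therefore demonstrate
that the chain recovers structure *of the planted kind* at realistic
amplitude ratios — they do not certify performance on real instrument
data, where MSC residuals and drift are less well behaved.

## Aquagrams

Spectra (SG + MSC, no Pareto) restricted to the analysis window are
z-scored per WAMAC channel across the whole comparison set; a group's
profile is the mean z-score of its spectra. Consequences asserted in the
tests: the size-weighted mean profile is zero at every coordinate, and
profiles are invariant to adding a common constant. The 11 default
coordinates (1342–1486 nm) use nearest-channel lookup, which is exact on
the 0.5 nm instrument grid; a coordinate farther than one grid step from
any channel is an error. A twelfth band around 1476–1512 nm can be added
by passing a custom WAMAC table. External reference spectra (e.g. pure
water) enter as a pseudo-group.

## Validation scheme

One fold per strain; the union of test sets is the whole dataset.
Preprocessing is refit inside every fold — the defensible default, and the
no-leakage property is asserted by corrupting held-out spectra and
checking the fold model is bit-identical. Strain calls are majority votes
over the strain's spectra; ties leave the strain unclassified (counted as
an error in strain-level accuracy). Both spectrum-level and strain-level
accuracies are reported because vote aggregation usually, but not always,
dominates: an unclassified tie can push strain accuracy below spectrum
accuracy.

The permutation-style null uses a generator configuration with one shared
archetype and zero group offsets. Note that one-strain-out is slightly
*anti*-conservative downward under the null: the held-out strain's class
has 4 training strains versus 5 for the others, biasing predictions away
from the true class, so null accuracy sits at or below 1/3. The chance-
level check therefore pools three seeded replicates (45 strain calls)
against the exact binomial 95% interval.

## The probioticity score

The four phenotype variables have incommensurate units (h⁻¹, OD, mg/ml,
ΔOD), so autoscaling is the default before the reference PCA; Pareto is
available because the choice is not neutral — on the built-in 15-strain
table autoscaling puts 76.5% of the variance on PC1 and Pareto 81.5%.
PC1's sign is fixed by its Spearman correlation with bile MIC, making
"higher = more probiotic" a construction rather than a convention to
remember.

## Numerical choices and degenerate inputs

* Wavelength grids must be strictly increasing and uniform (relative step
  tolerance 1e−6); duplicated or non-monotone wavelength columns are
  format errors naming the column.
* Delimited output formats doubles with 17 significant digits and input is
  parsed with base R's correctly-rounded reader, so tables round-trip at
  full precision.
* MSC rejects per-spectrum gains |b| < 1e−12; Pareto maps SD < 1e−12
  channels to 0; PLS refuses constant responses; PCA refuses
  k > min(n − 1, p).
* All fits are deterministic given row order: no random initialization
  anywhere, NIPALS starts from the first response column.

## Problem sizes used by the test suite

The suite exercises the same generative process as the full instrument
shape but at reduced grid/cadence so it runs in minutes: window-level
checks use the ten 4-min scans of the analysis window on a 2 nm grid
(150 × 376); the window-scan replicates use 80 scans at 15 min on a 5 nm
grid, 100 seeded replicates; the 290-window enumeration uses the full 300
scans on a 10 nm grid. The defaults of `sim_config()` remain the full
instrument shape (300 scans, 0.5 nm, 15 strains).

## Known limitations

* The 68–82% PC1 share of the reference PCA depends on the scaling
  convention; both options are exposed and the setting is always reported.
* OPLS-DA %X-variance bookkeeping follows this package's definitions
  (deflation-based, per component); other implementations partition
  variance differently, so those percentages are comparable only in shape.
* MSC is a first-order scatter model; wavelength-dependent scatter needs
  EMSC-type extensions that are out of scope (as are derivatives, SNV and
  wavelet denoising).
* The strain-level claims rest on 15 strains; the binomial intervals in
  the null checks are wide, and nothing here substitutes for validation on
  independent instrument data.
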