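---
title: "Estimating leaf SPAD from reflectance spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf SPAD from reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearspad)
```

## The problem

A SPAD meter reads relative leaf chlorophyll in one or two seconds, but
only leaf by leaf and by contact. Field spectroradiometers measure
reflectance `R(λ)` over 350–2500 nm without contact, and chlorophyll
leaves a strong signature there: absorption wells in the blue (~450 nm)
and red (~670 nm) and the steep "red edge" rise between ~680 and
~750 nm. A calibration from spectra to SPAD therefore enables rapid,
non-destructive chlorophyll monitoring — if the spectral noise can be
handled. In arid, dusty growing regions the dominant nuisance is
high-frequency, band-to-band noise from dust deposited on the leaf
surface, and separating that noise from the smooth pigment signal is the
core methodological question this package addresses.

`pearspad` implements the full chain: smoothing, spectral transforms, a
multi-level Haar discrete wavelet decomposition, correlation-based
sensitive-band extraction, and regression with held-out validation. The
field data such a study rests on are rarely public, so the package also
ships a synthetic generator that emulates the campaign's statistical
structure; every claim the test suite makes is made on that synthetic
ground truth.

## The synthetic generator: what it emulates

`generate_dataset(synthetic_config())` simulates a campaign of 87 canopy
leaves (22 east, 22 south, 22 west, 21 north). The latent SPAD of each
leaf is drawn from a normal with mean 45.8 and SD 3.64, truncated by
rejection to [32.6, 67.1] — the summary statistics of the emulated
campaign (implied coefficient of variation 7.95%). The recorded label
adds meter error with SD 0.5 SPAD units, reading the instrument's
"±1.0 SPAD units" accuracy as a 2-sigma bound, and is clamped to the
truncation bounds.

Reflectance on the 350–2500 nm, 1 nm grid is built additively:

* a continuum that rises logistically from 0.10 in the visible to 0.45
  in the NIR across a red edge centered at 715 nm (scale 15 nm);
* Gaussian absorption wells at 450 nm (sigma 40 nm) and 670 nm (sigma
  30 nm) whose depth is `0.0012 × SPAD` — the linear SPAD→depth map the
  recovery tests later invert;
* a smooth sample-specific drift: a random degree-3 Chebyshev
  polynomial scaled by `smooth_noise_sd` (default 0.003), standing in
  for leaf-structure and illumination variation;
* independent per-band Gaussian "dust" noise (`dust_noise_sd`, default
  0.002), the spectrally white component;

clipped to [0, 1]. One seed drives all randomness, so a config plus a
seed reproduces a dataset bit for bit.

Two calibration choices deserve a note. The sensitivity 0.0012 per SPAD
unit keeps the red well's reflectance positive at the maximum SPAD while
giving depth variation of the same order as the wells themselves. The
two noise SDs were chosen so that the peak per-band correlation with
SPAD lands near |r| ≈ 0.8–0.9 (peak r² ≈ 0.65–0.8), the regime reported
for real leaf campaigns of this size; they were fixed once, from that
argument, not adjusted against test outcomes.

What the generator does *not* emulate: radiative-transfer leaf optics
(no PROSPECT-style structure parameter), water absorption features,
canopy geometry, or instrument splice artifacts. Passing tests therefore
demonstrate that the pipeline's machinery is correct and that its
qualitative noise behavior holds under a plausible noise model — not
that any particular R² is attainable on real orchard data.

One consequence of the additive design is worth knowing when reading
stability results: dust is the *only* high-frequency component, so with
`dust_noise_sd = 0` the wavelet detail series are essentially
noise-free and detail-scale models can look spuriously excellent. The
moment any dust is present the detail scales degrade sharply while the
approximation scales barely move — that contrast, not the dust-free
detail performance, is the scientifically meaningful behavior.

## Preprocessing and transforms

Smoothing is a running median (`smooth_spectra`), default window 5 bands
with reflective edges: the smallest window that removes isolated dust
spikes without flattening the red edge. Analysis then restricts to a
400–1075 nm window by default — wide enough to contain every band the
visible/red-edge/NIR models use, while trimming the noisiest
spectroradiometer edges; the full range remains available via
`pipeline_config(window_nm = )`.

Six pointwise representations are supported: `R`, `1/R`, `log10 R`, and
their first derivatives by central differences over 2 nm with endpoints
dropped (symmetric, standard for 1 nm grids). Logarithms are base 10,
the spectroscopy convention; the base only rescales downstream
coefficients. Nonpositive reflectance (possible near the grid edges
after smoothing) is clipped at `1e-4` before `1/R` and `log R`, and the
count of clipped cells is carried on the result as an attribute.

## The Haar decomposition

`haar_dwt` applies the orthonormal Haar analysis step three times:
pairwise sums (approximation, `L`) and differences (detail, `H`) scaled
by `1/√2`. Orthonormal scaling makes Parseval exact — the squared sum of
`L3 ∪ H3 ∪ H2 ∪ H1` equals the squared sum of the input — which the
suite asserts to 1e-9 and cross-checks coefficient-by-coefficient
against an independent reference DWT to 1e-10. Odd lengths are
reflect-padded by one sample per level; pad positions are recorded and
excluded from the wavelength mapping. Each coefficient at level `j` is
reported at the mean of the `2^j` original wavelengths it covers, which
is what keeps "sensitive band (nm)" well-defined after the resolution
halves at every level (`len(L_j) = ceil(len(L_{j−1})/2)`).

Because dust noise is band-to-band independent, almost all of its energy
lands in `H1` (exactly all of it, for a pairwise alternating
perturbation), while the chlorophyll wells — dozens of nanometers wide —
survive into `L1`–`L3`. That is the mechanism behind the package's
central qualitative result.

## Band screening and selection

`correlate` computes the per-band Pearson correlation between the
transformed values and SPAD; bands with zero variance get `r = 0` and
are flagged rather than propagating `NA`. Pearson (not rank) correlation
is used because the downstream models are linear. By default the screen
uses only the modeling split — screening on all samples and then
validating on a subset would leak the validation labels into band
choice; a config switch (`correlate_on = "all"`) exists for comparison.

`select_bands` picks `k = 2` bands greedily: repeatedly the largest-|r|
band at least 50 nm from every band already chosen, ties to the shorter
wavelength. The 50 nm separation prevents selecting two adjacent, nearly
collinear bands from the same absorption feature and reproduces the
typical visible + red-edge pairing. The greedy rule is verified against
a brute-force search over all separation-feasible subsets on small
grids.

## Models and evaluation

The 87 samples are split 60/27 (modeling/validation) uniformly at
random under a fixed, logged seed (default 20250605).

Two model readings are implemented on the selected bands:

* **Two-band OLS** (`fit_two_band`): `y = b0 + b1 x_λ1 + b2 x_λ2`, the
  classical per-transform reporting style. Rank-deficient designs are
  rejected by name.
* **NIPALS PLS1** (`fit_pls`): centered (optionally scaled) predictors,
  weight/score/loading extraction with deflation, components capped at
  the design rank and chosen by leave-one-out RMSE on the modeling
  split. With a univariate response the NIPALS inner loop reaches its
  fixed point `w ∝ E'f` in one pass, so each component is evaluated in
  closed form; residual covariance below `1e-12` stops extraction with a
  diagnostic. At full rank PLS reproduces OLS, which the suite asserts,
  alongside agreement with an independent PLS implementation to 1e-6.

The pipeline default is PLS. The choice matters in one degenerate but
instructive case: on *noise-free* synthetic data every band is an exact
affine function of latent SPAD, so any two bands are exactly collinear
and the two-band OLS design is singular — correctly rejected. PLS
degrades gracefully to a single component there and fits the planted
model essentially exactly (end-to-end validation R² ≥ 0.99 in the
suite).

By default predictors and response are z-scored on the modeling split
before fitting. This reconciles coefficient magnitudes across
representations whose native scales differ by orders of magnitude
(reflectance ~0.3 vs derivative ~1e-3); coefficients are also
back-composed into original units and both are reported, with
predictions always in SPAD units. Metrics are the standard
`R² = 1 − SS_res/SS_tot` (computable negative on validation, as it
should be) and `RMSE` in SPAD units; both are checked against two-pass
reference formulas to 1e-12.

The comparison table ranks models by validation R² with ties to lower
validation RMSE. Training metrics are reported alongside but never used
for ranking — mixing the two is a common source of over-claimed
accuracy.

## Numerical and interface choices

* `run_pipeline` is deterministic: dataset + config + seeds →
  byte-identical comparison tables.
* Stage failures abort with the transform tag and stage name
  (`[H1/fit] …`), so a 12-transform run never half-succeeds silently.
* The wavelet decomposition for the six `L`/`H` tags is computed once
  per run and shared.
* All spectra I/O is plain wide CSV (wavelength column + one column per
  sample) with a separate labels table; values survive a round trip at
  ≥ 10 significant digits. No proprietary instrument formats are parsed.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated
data: campaign-scale datasets of 87 spectra × 2151 bands, 10,000-sample
draws for distributional checks, 100 random length-512 signals for the
DWT cross-checks, 50 dust-free replicates for band recovery, and 20
seeds × 4 transforms for the noise-stability comparison. These sizes
make every property statistically meaningful while keeping a full run in
the tens of seconds.

## Known limitations

* The generator's linearity (well depth strictly proportional to SPAD)
  makes recovery tests clean but is kinder than reality, where the
  SPAD–chlorophyll–reflectance chain saturates at high pigment loads.
* Band selection is greedy and pairwise-separated; it will not find
  complementary band *combinations* whose joint power exceeds their
  marginal correlations (no VIP scores or successive projections).
* The leave-one-out component choice is the only hyperparameter search;
  there is deliberately no wider model zoo.
* Validation uses a single random split, as in the emulated study
  design; users wanting tighter uncertainty should wrap
  `run_pipeline` over repeated splits, as `analysis/03_noise_stability.R`
  does over generator seeds.
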