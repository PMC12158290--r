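# pearspad

Estimating relative chlorophyll content (SPAD) of orchard leaves from
field reflectance spectra.

Leaf chlorophyll is the standard indicator of tree nutritional status,
and a handheld SPAD meter gives a fast relative reading of it. Full-range
(350–2500 nm) field spectra carry the same information non-destructively,
but in dusty growing regions the spectra are contaminated with
high-frequency noise that ruins naive band–trait regressions. `pearspad`
implements the chemometric chain that deals with this: median-filter
smoothing, classical spectral transforms, a multi-level Haar discrete
wavelet decomposition that separates low-frequency signal from
high-frequency noise, correlation-based sensitive-band extraction, and
two-band OLS / partial least squares calibration with held-out
validation. A synthetic spectra generator reproduces the statistical
structure of a pear-orchard campaign (87 canopy leaves, four compass
directions, SPAD mean 45.8 and SD 3.64), so the whole pipeline is
testable end to end without any field data.

## The method

For each candidate representation of the smoothed reflectance spectrum
`R(λ)` — the raw spectrum, `1/R`, `log10 R`, their central-difference
first derivatives, and the approximation (`L1`–`L3`) and detail
(`H1`–`H3`) series of a 3-level orthonormal Haar DWT

    a_j[i] = (x[2i−1] + x[2i]) / √2,   d_j[i] = (x[2i−1] − x[2i]) / √2

— the pipeline computes the per-band Pearson correlation with SPAD on a
random 60-sample modeling split, greedily selects the top-|r| bands
subject to a minimum 50 nm separation, fits a calibration on those bands
(NIPALS PLS1 with leave-one-out component choice by default, or a
two-band affine model `y = b0 + b1·x_λ1 + b2·x_λ2`), and scores it on the
27-sample validation split with

    R²   = 1 − Σ(CHLᵢ − CHLPᵢ)² / Σ(CHLᵢ − C̄HL)²
    RMSE = √( Σ(CHLᵢ − CHLPᵢ)² / n )

where `CHL` is the measured and `CHLP` the estimated SPAD value. Each
wavelet coefficient is reported at the mean wavelength of the `2^j` bands
it covers, so "sensitive band (nm)" stays meaningful at every scale.

## Worked example

```r
library(pearspad)
ds  <- generate_dataset(synthetic_config(seed = 20250605L))
res <- run_pipeline(ds)   # PLS on 2 selected bands, all 12 transforms
print(res)
```

```
# A tibble: 12 × 7
   transform_tag bands_nm      model     r2_train rmse_train r2_valid rmse_valid
 1 R             668, 452      y = 75.0…    0.676       1.78   0.771        1.77
 3 logR          668, 452      y = -37.…    0.669       1.80   0.744        1.87
 7 L1            668.5, 452.5  y = 75.4…    0.671       1.80   0.755        1.83
10 H1            1044.5, 964.5 y = 45.1…    0.265       2.69   0.149        3.41
...
winner: R (validation R^2 = 0.771, RMSE = 1.768)
```

Reading the table: every pointwise low-frequency representation (R,
logR, L1–L3) finds the chlorophyll absorption bands near 450 nm and
670 nm and validates around R² ≈ 0.74–0.77, while the detail-scale
(H1–H3) and derivative models are dominated by the simulated dust noise
and validate near or below zero — the wavelet approximation scales are
the stable choice, matching what the package's noise-stability analysis
(`analysis/03_noise_stability.R`) shows as dust increases.

The numbered scripts under `analysis/` run the study as a workflow:
`01_simulate.R` writes the campaign tables, `02_pipeline.R` writes the
12-row model comparisons (PLS and two-band OLS readings), per-transform
correlation profiles and measured-vs-predicted scatter data, and
`03_noise_stability.R` sweeps the dust-noise level to compare L- against
H-scale model stability. All outputs land under `results/`.

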