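# pgbm3d

Data-adaptive BM3D denoising for photon-limited two-photon microscopy (2PM)
images corrupted by mixed Poisson–Gaussian noise.

Intravital 2PM detects only a few photons per pixel, so images are dominated
by signal-dependent shot noise on top of Gaussian read-out noise:

    z(x) = α·Pois(y(x)) + N(μ_G, σ_G²),    E[z] = αy + μ_G,  Var[z] = α²y + σ_G²

Fluorescent nanoparticles appear as 1–2 px bright spots that closely resemble
the noise itself, which is exactly what generic AWGN denoisers destroy. This
package implements, for researchers analysing such data:

* **Noise model**: per-pixel Poisson–Gaussian simulation and calibration of
  (α, μ_G, σ_G) from dark frames and a flat-field intensity ladder, via the
  linear variance law `Var = α·(mean − μ_G) + σ_G²`.
* **Variance stabilization**: the generalized Anscombe root transform
  `f(z) = (2/α)·sqrt(αz + 3α²/8 + σ_G² − αμ_G)` with its exact unbiased
  inverse (tabulated `E[f(z)|y]`, monotone spline inversion), plus algebraic
  and asymptotic inverses as baselines.
* **Two-level BM3D collaborative filter** with two data-adaptive changes:
  a noise-adaptive block-matching threshold
  `Th_BM = 2σ_η² + Th_offset` (level 1; the noise term is reduced to 30 %
  at level 2), and per-subband BayesShrink *hard* thresholding
  `Th_Bayes = σ²/σ̂_y` on a non-standard (quadrant) Haar decomposition whose
  subbands are large enough for reliable σ̂_y estimation. An
  original-BM3D baseline mode (raw-domain, global σ, fixed 2.7σ threshold
  and fixed matching thresholds) is included for comparison.
* **Evaluation harness**: seeded synthetic phantoms (cell mosaics,
  nanoparticle fields, edge targets, flat fields), grayscale 8/16-bit TIFF
  I/O, and MSE / MS-SSIM / sharpness-index curves across a noise grid, as
  tidy tibbles with `autoplot()` methods.

## Worked example

Calibrate the noise model from simulated calibration data, then denoise a
noisy cell-mosaic phantom:

```r
library(pgbm3d)

## -- calibration from dark frames + a 24-level flat-field ladder ----------
truth <- noise_params(1.2, mu_g = 8, sigma_g = 3)
darks <- lapply(1:3, function(i)
  simulate_pg_noise(matrix(0, 256, 256), truth, seed = i))
gauss <- estimate_gaussian_params(darks)
levels <- seq(20, 2000, length.out = 24)
flats <- lapply(seq_along(levels), function(i)
  simulate_pg_noise(matrix(levels[i], 256, 256), truth, seed = 100 + i))
fit <- calibrate_alpha(calibration_series(flats, levels, darks), gauss)
fit
#> <pg_calibration> alpha = 1.202 (R^2 = 0.9999) over 24 flat-field levels
glance(fit)
#> # A tibble: 1 × 5
#>   alpha  mu_g sigma_g r_squared n_levels
#>   <dbl> <dbl>   <dbl>     <dbl>    <int>
#> 1  1.20  8.00    3.01     1.000       24
```

The gain is recovered to 0.2 % and the variance-versus-intensity fit is
essentially perfect — the heteroscedastic model describes the data.
`autoplot(fit)` draws the variance-vs-mean curve with the fitted line.

```r
## -- denoising a photon-limited phantom -----------------------------------
g    <- make_phantom("cells", 256, seed = 7)       # ground truth, counts
gain <- 40                                         # counts per photon
p    <- noise_params(gain, mu_g = 8, sigma_g = 3)
z    <- simulate_pg_noise(g / gain, p, seed = 11)  # ~100 photons at peak
est  <- gain * denoise(z, p, denoise_config("modified"))

mse(z - 8, g);  mse(est, g)
#> [1] 67632
#> [1] 11676
ms_ssim(z - 8, g, dynamic_range = 4095); ms_ssim(est, g, dynamic_range = 4095)
#> [1] 0.9307
#> [1] 0.9775
```

The mean squared error drops by 5.8× and MS-SSIM rises from 0.93 to 0.98:
the stabilize–filter–invert chain removes most of the shot noise while
keeping the mosaic's membranes and granular texture.

To compare the adaptive mode against the original-BM3D baseline across a
noise grid:

```r
ev <- evaluate_curves(phantom_suite(size = 256), c(0.5, 1, 2, 4), seed = 1)
relative_curves(ev)   # per-phantom MSE/MS-SSIM ratios, SI differences
autoplot(ev)          # metric-vs-1/α curves, one trace per phantom and mode
```

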