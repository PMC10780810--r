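# msfadesign

Simulation and design toolkit for snapshot **multispectral-filter-array
(MSFA) cameras** aimed at plant and vegetation imaging (crop/weed
separation, ripeness and disease detection). An MSFA generalizes the Bayer
pattern: a 4×4 *moxel* of narrow-band interference filters is deposited
pixel-wise on a monochrome CMOS sensor, so a single exposure carries 8
spectral bands (two pixels per band per moxel). A dual-camera design — one
visible-range MSFA (380–680 nm) and one near-infrared MSFA (650–950 nm) —
yields 16 bands in one snapshot pair.

The package is for imaging scientists and camera designers who need to
answer, **before fabrication**: which band centers should the filters
have, how well can full reflectance spectra be recovered from 8 band
responses, how do mosaicking and demosaicking degrade the image, and how
will the finished hybrid sensor be characterized and balanced.

## The model

**Forward imaging chain.** For filter *i* and reflectance sample *r_k*,
the camera response is

    O[i,k] = Σ_λ S(λ) u_i(λ) E(λ) r_k(λ) Δλ

with *S* the sensor quantum efficiency, *u_i* the filter transmission,
*E* the illuminant SPD. Filters follow the peak-normalized Gaussian model

    u(λ) = α exp( −(λ−μ)² / 2σ² ),   σ = FWHM / (2√(2 ln 2))

with design FWHM 30 nm during band selection; α is the peak transmission
Tmax that fabrication is specified against (> 40 %).

**Reconstruction.** Spectra are recovered by the linear
minimum-mean-squared-error (Wiener) estimator

    r̂_k = W O_k,   W = C_r Aᵀ (A C_r Aᵀ + v I)⁻¹

where *A* is the system matrix above, *C_r* the (uncentered) second-moment
matrix of a training reflectance library and *v* the noise variance
(SNR = 100 additive white Gaussian noise by default).

**Band selection.** A real-coded island genetic algorithm (population 100,
crossover fraction 0.6, migration fraction 0.2, fitness limit 0.02)
searches for the band centers minimizing the mean per-sample RMS of the
Wiener reconstruction. Quality is reported as RMS, the goodness-of-fit
coefficient GFC = |⟨r, r̂⟩| / (‖r‖‖r̂‖), and CIEDE2000.

**Image formation.** `mosaic()` / `demosaic_bilinear()` simulate the
snapshot acquisition and its two-pass bilinear reconstruction (the 4×4
masks tile N_l × N_c = 300 × 400 times over the 1600×1200 sensor);
`white_calibrate()` converts to reflectance factors against a Lambertian
white; `energy_balance()` computes the per-band gains that equalize
channels under an illuminant; `simulate_sweep()` +
`characterization_report()` emulate the monochromator bench (5 nm steps)
that measures (centering, FWHM, Tmax) of the finished sensor.

Because the original 626-sample reflectance library of eight species is
not deposited, `gen_reflectance_set()` provides a seeded vegetation-like
stand-in (green peak, chlorophyll absorption wells, sigmoidal red edge,
NIR plateau, species-level cluster structure).

## Worked example

```r
library(msfadesign)
grid <- wl_grid()                                  # 380-1000 nm, 1 nm
ds   <- gen_reflectance_set(veg_params(seed = 1), grid)   # 626 spectra
qe   <- gen_sensor_qe(grid)
bank <- measured_bank("VIS", grid)                 # fabricated VIS MSFA
A    <- system_matrix(qe, bank, standard_illuminant("A", grid))
O    <- camera_response(A, ds, snr = 100, seed = 1)
est  <- fit_wiener(A, ds, noise_variance = O$noise_sd^2)
evaluate(ds, reconstruct(est, O))
#> <reconstruction_report>
#>                min    max   mean median    std
#> rms         0.0078 0.1975 0.0684 0.0631 0.0423
#> gfc         0.9790 0.9998 0.9969 0.9982 0.0032
#> delta_e2000 0.0255 1.6672 0.5440 0.4812 0.3013
#> GFC > 0.99: 95.4%   GFC > 0.95: 100.0%
```

Reading: through the 8 fabricated VIS filters, the average spectrum is
recovered with 0.068 RMS reflectance error over the full 380–1000 nm
grid, 95 % of samples are nearly proportional to the truth (GFC > 0.99),
and the mean perceptual colour error is ≈ 0.5 ΔE₀₀ — far below the ~2.3
just-noticeable-difference threshold.

Characterizing the NIR prototype on the simulated monochromator bench
recovers the fabrication parameters:

```r
stack <- simulate_sweep(gen_sensor_qe(grid), measured_bank("NIR", grid),
                        380, 1000, 5)
characterization_report(estimate_filter_response(stack))
#>  band centering     fwhm tmax
#>    P1       670 31.08579 0.55
#>    P2       705 30.00000 0.53
#>    ...
#>    P8       885 27.09936 0.47
```

Band selection for a new camera:

```r
res <- run_ga(ds, ga_settings(seed = 0, max_generations = 25))
res$centers        # 8 optimized band centers (nm)
res$report         # RMS / GFC / CIEDE2000 of the winning bank
```

A command-line front end (`inst/cli/msfa.R`) exposes the stages
(`gen-data`, `select-bands`, `simulate-scene`, `demosaic`,
`characterize`, `balance`, `report`) driven by a JSON run configuration;
every artifact is written with a provenance sidecar.

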