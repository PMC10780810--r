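---
title: "Methods: simulating and designing snapshot MSFA cameras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and designing snapshot MSFA cameras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfadesign)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic data does and
does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The imaging chain and its assumptions

A snapshot MSFA camera observes a reflectance spectrum $r_k(\lambda)$
through $n$ narrow-band filters. The band response is modeled as

$$ O_{i,k} \;=\; \sum_\lambda S(\lambda)\, u_i(\lambda)\, E(\lambda)\,
   r_k(\lambda)\, \Delta\lambda $$

with $S$ the sensor quantum efficiency, $u_i$ the filter transmission and
$E$ the illuminant spectral power distribution. Assumptions: the chain is
linear (no saturation, no dark current, no shot noise), all curves live
on one common wavelength grid (default 380–1000 nm at 1 nm), and spectral
integrals use the rectangle rule with weight $\Delta\lambda$, folded into
the system matrix so that the forward model and the energy-balance
integral share one quadrature convention. The default grid's 1 nm
resolution is an assumption — fine enough that the 30 nm-wide filters are
sampled by dozens of points, and the characterization bench's 5 nm sweep
is a strict sub-grid.

Filters follow the peak-normalized Gaussian transmission model

$$ u(\lambda) = \alpha\, e^{-(\lambda-\mu)^2 / 2\sigma^2},
   \qquad \sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}). $$

A unit-area (density-normalized) Gaussian was deliberately rejected:
fabricated interference filters are specified by their *peak*
transmission $T_{\max}$ (over 40 % for all sixteen fabricated bands), and
$\alpha$ maps directly onto that quantity while a density prefactor could
not. The packaged measured banks (`measured_bank("VIS")`, 425–660 nm, and
`measured_bank("NIR")`, 670–885 nm) are Gaussian idealizations built from
the measured (centering, FWHM, $T_{\max}$) triples; real curves show
asymmetries and side lobes that no tabulated data exist for, so the
Gaussian shape is an approximation by necessity, not a claim.

## Noise model

`camera_response()` adds white Gaussian noise with a single standard
deviation $\sigma_n = \overline{|O|}/\mathrm{SNR}$ shared across
channels, SNR = 100 by default. This is the simplest law consistent with
"additive normally distributed white noise at SNR 100"; no per-channel
scaling is assumed. One consequence worth knowing: for a *single* band
the reconstruction problem becomes scale-invariant (scaling the band
scales signal and noise alike), so single-band selection is only
discriminative when the spectral variation has rank greater than one —
the test suite constructs its window-recovery fixtures accordingly.

## Wiener reconstruction

The estimator is the linear MMSE solution

$$ \hat r_k = W O_k, \qquad
   W = C_r A^\top \left( A C_r A^\top + v I \right)^{-1}, $$

with $C_r = K^{-1}\sum_k r_k r_k^\top$ the **uncentered** second-moment
matrix of the training library — uncentered because the reconstruction
formula carries no mean-offset term. The normal matrix is solved by
Cholesky factorization, never an explicit inverse (tests use the explicit
inverse as the independent oracle). A singular system at $v = 0$ raises
an error advising a positive noise variance rather than silently
regularizing. Estimates are not clipped to $[0,1]$ unless requested:
metrics are computed on the raw linear estimate.

## Evaluation metrics

Per sample: RMS $\sqrt{\mathrm{mean}((r-\hat r)^2)}$; the goodness-of-fit
coefficient $\mathrm{GFC} = |\langle r,\hat r\rangle| /
(\|r\|\,\|\hat r\|)$ (scale-invariant, 1 = proportional match); and
CIEDE2000. The colour pathway converts reflectance to CIE XYZ under a
chosen illuminant with the 1931 2° observer, then to CIELAB with the
illuminant white point. Two documented approximations:

* The colour-matching functions use the published multi-lobe
  piecewise-Gaussian analytic fit of the 1931 2° observer instead of a
  re-typed 81-row table. The fit errs by a few percent of peak — ample
  for a *relative* reconstruction metric — whereas hand-transcribing
  three 81-value curves invites silent errors. The CIEDE2000 formula
  itself is exact and validated against the complete 34-pair published
  verification set to $10^{-4}$.
* For NIR-range spectra the metric is computed on the overlap of the grid
  with the 380–780 nm observer support, and the report flags
  `partial_cmf_support`. A grid with no overlap is an error. This makes
  the colour difference for a NIR camera *well-defined and auditable*; it
  is a package convention, not an inference about how such numbers were
  obtained elsewhere.

Illuminants: A (Planck 2856 K, exact by definition), E (flat), tungsten
(Planck 3200 K), and a "D65" solar-simulator surrogate (Planck 6504 K).
The CIE D65 table stops at 830 nm and cannot describe the NIR, which is
precisely the range this design targets; a smooth full-range surrogate
with the correct correlated colour temperature was preferred over a
truncated table. Code that needs the exact D65 table below 830 nm should
load it as a spectra CSV.

## Genetic-algorithm band selection

The fitness of a candidate center vector is the mean per-sample RMS of
the Wiener reconstruction through a Gaussian bank at those centers
(FWHM 30 nm, $\alpha = 1$ during search — peak transmission is a
fabrication outcome, not a design variable), under the settings' SNR with
a fixed noise substream so fitness is a pure function of the centers.

Stated search settings: population 100, crossover fraction 0.6, migration
fraction 0.2, fitness limit 0.02 RMS. Everything else was open and is a
package design choice:

* **Encoding** — real-valued sorted center vector (centers are what the
  Gaussian model exposes).
* **Selection** — tournament of 3, two elites preserved per island.
* **Crossover** — per-gene blend (convex combination with uniform
  weights) on 60 % of offspring.
* **Mutation** — per-gene Gaussian perturbation, sd 5 nm, rate
  $1/n_\text{bands}$, on the remaining offspring.
* **Islands** — two demes on a ring exchanging the best 20 % every 10
  generations ("migration fraction" presupposes demes; the topology was
  unstated).
* **Repair** — sort, clip to bounds, enforce a 10 nm minimum spacing
  (prevents duplicate bands); with a discrete candidate set, genes snap
  to the nearest unused candidate instead, which is the mode validated
  against exhaustive search.
* **Termination** — fitness limit or a 200-generation cap (no cap was
  stated; the history of best/mean fitness is returned for inspection).

Search-range presets: VIS 380–680 nm, NIR 650–950 nm. The default
forward-model illuminant during selection is A — the illuminant the
emulated reflectance library was measured under — and is configurable.
The exact fabricated center sets are *not* a reproduction target: they
depend on the original undeposited library.

## Mosaicking and demosaicking

The moxel is a 4×4 band-index pattern, two pixels per band, duplicates
offset by two rows and two columns for quasi-uniform sampling. The true
fabricated arrangement is not recoverable from any tabulated source, so
layouts are *data* (4 lines of 4 integers) with that documented default.
Unequal multiplicities (e.g. extra pixels for weak bands beyond 850 nm)
are representable with `strict = FALSE` but not assumed.

Demosaicking implements "linear interpolation in both main directions"
as a symmetric two-pass rule: estimate A interpolates along rows that
contain samples of the band, then completes along columns; estimate B
does columns first, then rows; the output is their average, with sampled
pixels kept exactly and nearest-sample extension beyond the outermost
samples of a line. The rule is deliberately simple (no edge-aware or
frequency-domain machinery) and is locked by a straight-loop brute-force
oracle to $10^{-12}$, exactness on constants, and 4-pixel translation
equivariance.

The cosine test scenes draw periods from 24–64 px. Each band samples a
line every 4 px, so 24 px keeps at least 6 samples per period — the
smoothness regime in which bilinear interpolation is meaningful and the
35 dB PSNR regression target is attainable; sharper content is the
documented failure mode of bilinear demosaicking, not a regression.

White calibration divides by a Lambertian-white cube with an
$\varepsilon$ floor (default $10^{-6}$) so dead white pixels produce
bounded, finite output.

## Monochromator-sweep characterization

`simulate_sweep()` models the bench: monochromatic line stepped at 5 nm
(default 300–1000 nm, 141 points), bare-sensor response recorded first,
then per-band hybrid responses; the monochromator's own 0.25 nm line
width is treated as a delta against 5 nm steps, and constant integration
time as unit gain. `estimate_filter_response()` divides band by bare
response wherever the bare signal is at least 5 % of its maximum
(default floor; below it the estimate is masked rather than amplified
into garbage), clipping to $[0, 1.05]$. `characterization_report()`
measures centering (argmax; plateau ties break to the lower wavelength
with a warning), $T_{\max}$, and FWHM by linearly interpolated
half-maximum crossings. The noiseless round trip recovers both packaged
banks within (one sweep step, two sweep steps, 2 %).

## The synthetic vegetation library

The generator emulates a 626-sample, 8-species crop-and-weed reflectance
library that is not publicly deposited. Each species draws an archetype —
visible baseline 0.03–0.08, chlorophyll absorption wells near 450 and
670 nm, green peak near 550 nm (height 0.05–0.14, width 25–35 nm),
sigmoidal red edge inflecting at 700–725 nm with slope scale 8–15 nm,
NIR plateau 0.3–0.6 — and each sample perturbs its archetype (10 % of
each range) plus smooth noise (25 nm knots, spline-interpolated, sd 0.01
reflectance units; the source instrument's noise was unreported, so a
conservative smooth term was chosen once). Values are clipped to [0, 1];
seeded runs are bit-reproducible.

What a green test on this library establishes: the *pipeline* — forward
model, estimator, optimizer, metrics — behaves correctly on data with
realistic amplitude, smoothness, correlation length and cluster
structure. What it does not establish: performance on real leaf optics
(no radiative transfer, no specular/geometry effects, no water
absorption features around 970 nm, no inter-species spectral overlap
pathologies), and no reproduction of any previously published summary
statistics, which depended on the original library.

## Numerical conventions

* Wavelengths in nm everywhere; inclusive grid endpoints; resampling is
  linear and refuses extrapolation.
* Reflectance/transmission containers tolerate $10^{-6}$ overshoot and
  clamp tiny negatives to zero; anything larger errors.
* Matrix solves via Cholesky; symmetric matrices are symmetrized before
  factorization to absorb round-off.
* Seeds: every stochastic entry point takes an explicit integer seed;
  the pipeline fans one global seed out by fixed per-stage offsets; the
  GA fitness uses a fixed noise substream derived from the settings seed
  and restores the caller's RNG state.
* Degenerate inputs fail loudly: zero vectors in GFC, zero-response
  bands in energy balance, all-masked sweeps, non-divisible image
  dimensions, bounds too narrow for the requested band count.

## Known limitations

* Gaussian filter shapes ignore Fabry–Pérot rejection bands, harmonics
  and crosstalk; these are flagged bench concerns with no quantitative
  model available.
* The colour pathway's CMF fit and D65 surrogate trade a few percent of
  absolute colorimetric accuracy for robustness; absolute colorimetry is
  out of scope.
* On-disk image formats are plain-text PGM/CSV (no binary-image package
  is available in the target environment); files are larger than TIFF
  but lossless at 16-bit quantization.
* The GA is a serial reference implementation; fitness evaluation
  dominates runtime (one dense solve per candidate) and is sized for
  desk-scale studies, not production sweeps.
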