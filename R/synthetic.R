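# Seeded generators for everything the design study used but did not
# deposit: a vegetation-like reflectance library with species structure, a
# plausible CMOS QE curve, and synthetic test scenes for demosaicking.
#
# Vegetation archetype (emulation, not leaf physics): low visible baseline
# with chlorophyll absorption wells near 450 and 670 nm, a green peak near
# 550 nm, a sigmoidal red edge between ~690 and 740 nm, and a NIR plateau
# at 0.3-0.6 reflectance. Species draw archetype parameters; samples
# perturb them and add smooth low-amplitude noise.

#' Parameters of the vegetation reflectance generator
#'
#' Ranges are species-archetype draws; per-sample variation uses a fixed
#' fraction of each range. Defaults emulate a 626-sample, 8-species crop
#' and weed library.
#'
#' @param n_samples Total samples (default 626).
#' @param n_species Number of species clusters (default 8).
#' @param seed Integer seed.
#' @param noise_std Standard deviation of the smooth per-sample noise in
#'   reflectance units (default 0.01).
#' @param green_center,green_width Green-peak center / width ranges (nm).
#' @param green_height Green-peak height range above the baseline.
#' @param red_edge_center,red_edge_slope Red-edge inflection (nm) and
#'   logistic slope scale (nm) ranges.
#' @param nir_plateau NIR plateau reflectance range.
#' @param baseline Visible baseline reflectance range.
#' @param well_depth Fractional depth of the 450/670 nm absorption wells.
#' @return An object of class `veg_params`.
#' @export
veg_params <- function(n_samples = 626, n_species = 8, seed = 1,
                       noise_std = 0.01,
                       green_center = c(545, 560), green_width = c(25, 35),
                       green_height = c(0.05, 0.14),
                       red_edge_center = c(700, 725),
                       red_edge_slope = c(8, 15),
                       nir_plateau = c(0.3, 0.6),
                       baseline = c(0.03, 0.08),
                       well_depth = c(0.3, 0.6)) {
  stopifnot(n_samples >= 1, n_species >= 1, noise_std >= 0)
  p <- list(n_samples = n_samples, n_species = n_species, seed = seed,
            noise_std = noise_std, green_center = green_center,
            green_width = green_width, green_height = green_height,
            red_edge_center = red_edge_center,
            red_edge_slope = red_edge_slope, nir_plateau = nir_plateau,
            baseline = baseline, well_depth = well_depth)
  rng_ok <- vapply(p[5:12], function(r) length(r) == 2 && r[1] <= r[2],
                   logical(1))
  if (!all(rng_ok)) stop("veg_params: ranges must be (lo, hi) with lo <= hi")
  if (p$nir_plateau[2] + p$noise_std * 4 > 1) {
    stop("veg_params: parameters push reflectance above 1")
  }
  structure(p, class = "veg_params")
}

runif_rng <- function(r, n = 1) stats::runif(n, r[1], r[2])

# one spectrum from explicit archetype parameters; guaranteed smooth
veg_curve <- function(wl, base, gc, gw, gh, rec, res, nir, wd) {
  vis <- base + gh * exp(-((wl - gc)^2) / (2 * gw^2))
  vis <- vis * (1 - wd * exp(-((wl - 450)^2) / (2 * 22^2))
                  - wd * exp(-((wl - 670)^2) / (2 * 18^2)))
  edge <- 1 / (1 + exp(-(wl - rec) / res))
  vis + (nir - vis) * edge
}

#' Generate a vegetation-like reflectance dataset
#'
#' Species-level archetypes are drawn from the parameter ranges; each
#' sample perturbs its species archetype (10% of each range) and adds
#' smooth noise (coarse 25 nm knots, spline-interpolated, sd `noise_std`).
#' Values are clipped to [0, 1]. Deterministic for a given seed.
#'
#' @param params A [veg_params()].
#' @param grid A [wl_grid()] (default 380-1000 nm, 1 nm).
#' @return A [reflectance_set()] with species labels `sp1`...`spN`.
#' @export
gen_reflectance_set <- function(params = veg_params(), grid = wl_grid()) {
  stopifnot(inherits(params, "veg_params"))
  set.seed(as.integer(params$seed))
  wl <- wavelengths(grid)
  p <- params
  arch <- lapply(seq_len(p$n_species), function(s) {
    list(base = runif_rng(p$baseline), gc = runif_rng(p$green_center),
         gw = runif_rng(p$green_width), gh = runif_rng(p$green_height),
         rec = runif_rng(p$red_edge_center),
         res = runif_rng(p$red_edge_slope), nir = runif_rng(p$nir_plateau),
         wd = runif_rng(p$well_depth))
  })
  species <- rep(seq_len(p$n_species), length.out = p$n_samples)
  jit <- function(v, r) v + stats::rnorm(1, sd = 0.1 * (r[2] - r[1]))
  clipr <- function(v, r) min(max(v, r[1]), r[2])
  knots <- seq(grid$start, grid$stop, by = 25)
  if (knots[length(knots)] < grid$stop) knots <- c(knots, grid$stop)
  samples <- t(vapply(seq_len(p$n_samples), function(k) {
    a <- arch[[species[k]]]
    r <- veg_curve(wl,
                   clipr(jit(a$base, p$baseline), p$baseline),
                   clipr(jit(a$gc, p$green_center), p$green_center),
                   clipr(jit(a$gw, p$green_width), p$green_width),
                   clipr(jit(a$gh, p$green_height), p$green_height),
                   clipr(jit(a$rec, p$red_edge_center), p$red_edge_center),
                   clipr(jit(a$res, p$red_edge_slope), p$red_edge_slope),
                   clipr(jit(a$nir, p$nir_plateau), p$nir_plateau),
                   clipr(jit(a$wd, p$well_depth), p$well_depth))
    if (p$noise_std > 0) {
      kv <- stats::rnorm(length(knots), sd = p$noise_std)
      r <- r + stats::spline(knots, kv, xout = wl)$y
    }
    pmin(pmax(r, 0), 1)
  }, numeric(grid$n)))
  reflectance_set(grid, samples, labels = sprintf("sp%d", species))
}

#' Generate a plausible CMOS quantum-efficiency curve
#'
#' Smooth unimodal curve peaking between 500 and 600 nm and declining
#' monotonically beyond the peak toward 1000 nm (the silicon gain falls
#' toward the IR), strictly positive on the grid. Asymmetric-Gaussian
#' shape.
#'
#' @param grid A [wl_grid()].
#' @param peak_wl Peak wavelength (nm, default 545).
#' @param peak_qe Peak quantum efficiency (default 0.55).
#' @param width_left,width_right Left / right Gaussian widths (nm).
#' @return A [spectrum_curve()] of kind `"qe"`.
#' @export
gen_sensor_qe <- function(grid = wl_grid(), peak_wl = 545, peak_qe = 0.55,
                          width_left = 110, width_right = 230) {
  stopifnot(peak_wl >= 500, peak_wl <= 600, peak_qe > 0, peak_qe <= 1)
  wl <- wavelengths(grid)
  s <- ifelse(wl < peak_wl, width_left, width_right)
  spectrum_curve(grid, peak_qe * exp(-((wl - peak_wl)^2) / (2 * s^2)),
                 kind = "qe")
}

#' Generate a synthetic spectral test scene
#'
#' @param height,width Scene dimensions, divisible by 4.
#' @param n_bands Number of band planes (default 8).
#' @param kind Scene family: `"constant"` (all planes `value`), `"ramp"`
#'   (plane b is `offsets[b] + 0.001 x + 0.002 y`, 0-based coordinates),
#'   `"cosine"` (band-limited 2-D cosines, periods drawn from 24-64 px), or
#'   `"vegetation_patches"` (rectangular patches whose per-band values are
#'   vegetation spectra from [gen_reflectance_set()] seen through a
#'   measured filter bank and QE).
#' @param seed Integer seed.
#' @param value Constant level for `kind = "constant"` (default 0.25).
#' @return H x W x n_bands numeric array in [0, 1] (linear units).
#' @export
gen_scene <- function(height, width, n_bands = 8,
                      kind = c("constant", "ramp", "cosine",
                               "vegetation_patches"),
                      seed = 1, value = 0.25) {
  kind <- match.arg(kind)
  if (height %% 4 != 0 || width %% 4 != 0) {
    stop("gen_scene: height and width must be divisible by 4")
  }
  set.seed(as.integer(seed))
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), width), height, width)
  cube <- array(0, c(height, width, n_bands))
  if (kind == "constant") {
    cube[] <- value
  } else if (kind == "ramp") {
    offsets <- seq(0.05, 0.3, length.out = n_bands)
    for (b in seq_len(n_bands)) {
      cube[, , b] <- offsets[b] + 0.001 * x + 0.002 * y
    }
  } else if (kind == "cosine") {
    # periods >= 24 px keep >= 6 band samples per period along each axis
    # (band sampling pitch is 4 px), the smoothness the bilinear rule needs
    for (b in seq_len(n_bands)) {
      px <- sample(24:64, 1); py <- sample(24:64, 1)
      phx <- stats::runif(1, 0, 2 * pi); phy <- stats::runif(1, 0, 2 * pi)
      cube[, , b] <- 0.5 + 0.2 * cos(2 * pi * x / px + phx) *
                           cos(2 * pi * y / py + phy)
    }
  } else {
    grid <- wl_grid()
    ds <- gen_reflectance_set(veg_params(n_samples = 16, n_species = 4,
                                         seed = seed), grid)
    bank <- measured_bank("VIS", grid)
    A <- system_matrix(gen_sensor_qe(grid), bank,
                       standard_illuminant("E", grid))
    O <- camera_response(A, ds, snr = Inf)$responses
    O <- O / max(O)
    n_patch <- 4
    ph <- height / n_patch; pw <- width / n_patch
    k <- 0
    for (i in seq_len(n_patch)) for (j in seq_len(n_patch)) {
      k <- k + 1
      spec <- O[, ((k - 1) %% ncol(O)) + 1]
      for (b in seq_len(min(n_bands, length(spec)))) {
        cube[seq((i - 1) * ph + 1, i * ph),
             seq((j - 1) * pw + 1, j * pw), b] <- spec[b]
      }
    }
  }
  cube
}
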