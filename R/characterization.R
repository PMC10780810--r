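# Simulated monochromator-sweep characterization of a hybrid sensor.
#
# The bench procedure: sweep a monochromatic line in 5 nm steps, record the
# bare sensor response, then the hybrid (filter-on-sensor) response per
# band; the filter transmission is the ratio of the two wherever the bare
# signal is usable. The monochromator line (0.25 nm FWHM) is treated as an
# ideal delta against 5 nm steps, and constant integration time as unit
# gain.

#' Simulate a monochromator sweep
#'
#' @param qe Sensor QE [spectrum_curve()].
#' @param bank A [filter_bank()] mounted on the sensor.
#' @param start,stop,step Sweep range and step in nm (defaults 300-1000 in
#'   5 nm steps). The sweep is clipped to the support of the curves.
#' @param snr Optional signal-to-noise ratio for additive Gaussian noise on
#'   all recorded responses (same law as [camera_response()]); `Inf` =
#'   noiseless.
#' @param seed Seed for the noise draw.
#' @return An object of class `sweep_stack`: `wavelengths`,
#'   `bare_response`, `band_responses` (`n_bands x n_wavelengths`),
#'   `band_names`.
#' @export
simulate_sweep <- function(qe, bank, start = 300, stop = 1000, step = 5,
                           snr = Inf, seed = NULL) {
  stopifnot(inherits(qe, "spectrum_curve"), inherits(bank, "filter_bank"))
  if (step <= 0) stop("simulate_sweep: step must be > 0")
  lo <- max(start, qe$grid$start, bank$grid$start)
  hi <- min(stop, qe$grid$stop, bank$grid$stop)
  if (lo >= hi) stop("simulate_sweep: sweep range outside curve support")
  wl <- seq(lo, hi, by = step)
  qv <- stats::approx(wavelengths(qe$grid), qe$values, wl, rule = 1)$y
  bare <- qv
  B <- t(vapply(bank$bands, function(b) {
    qv * stats::approx(wavelengths(bank$grid), b$values, wl, rule = 1)$y
  }, numeric(length(wl))))
  if (is.finite(snr)) {
    if (snr <= 0) stop("simulate_sweep: snr must be > 0")
    sd <- mean(abs(c(bare, B))) / snr
    if (!is.null(seed)) set.seed(as.integer(seed))
    bare <- pmax(bare + stats::rnorm(length(bare), sd = sd), 0)
    B <- pmax(B + matrix(stats::rnorm(length(B), sd = sd), nrow(B), ncol(B)), 0)
  }
  structure(list(wavelengths = wl, bare_response = bare,
                 band_responses = B, band_names = bank$names),
            class = "sweep_stack")
}

#' Estimate filter transmissions from a sweep stack
#'
#' Divides each band response by the bare-sensor response wherever the
#' bare signal is at least `floor` of its maximum; elsewhere the estimate
#' is masked (`NA`). Results are clipped to [0, 1.05].
#'
#' @param stack A [simulate_sweep()] stack.
#' @param floor Usable-signal threshold as a fraction of the bare maximum,
#'   in (0, 1) (default 0.05).
#' @return A list of class `estimated_bank`: `wavelengths`, `transmissions`
#'   (`n_bands x n_wavelengths`, `NA` where masked), `band_names`, `floor`.
#' @export
estimate_filter_response <- function(stack, floor = 0.05) {
  stopifnot(inherits(stack, "sweep_stack"))
  if (floor <= 0 || floor >= 1) {
    stop("estimate_filter_response: floor must lie in (0, 1)")
  }
  ok <- stack$bare_response >= floor * max(stack$bare_response)
  if (!any(ok)) {
    stop("estimate_filter_response: bare response everywhere below floor")
  }
  Tm <- sweep(stack$band_responses, 2, stack$bare_response, "/")
  Tm[, !ok] <- NA_real_
  Tm <- pmin(pmax(Tm, 0), 1.05)
  structure(list(wavelengths = stack$wavelengths, transmissions = Tm,
                 band_names = stack$band_names, floor = floor),
            class = "estimated_bank")
}

# half-maximum crossing width with linear interpolation between samples
fwhm_from_curve <- function(wl, v) {
  i0 <- which.max(v)
  half <- v[i0] / 2
  left <- NA_real_
  if (i0 > 1) for (i in i0:2) {
    if (v[i - 1] < half && v[i] >= half) {
      left <- wl[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) *
        (wl[i] - wl[i - 1])
      break
    }
  }
  right <- NA_real_
  if (i0 < length(v)) for (i in i0:(length(v) - 1)) {
    if (v[i] >= half && v[i + 1] < half) {
      right <- wl[i] + (v[i] - half) / (v[i] - v[i + 1]) * (wl[i + 1] - wl[i])
      break
    }
  }
  if (is.na(left)) left <- wl[1]
  if (is.na(right)) right <- wl[length(wl)]
  right - left
}

#' Characterize an estimated filter bank
#'
#' Per band: centering = wavelength of the maximum transmission (plateau or
#' equal-peak ties broken toward the lower wavelength, with a warning),
#' Tmax = maximum transmission, FWHM = width of the region above half
#' maximum with linearly interpolated crossings.
#'
#' @param est An [estimate_filter_response()] result or a [filter_bank()].
#' @return data.frame with columns `band`, `centering`, `fwhm`, `tmax`
#'   (columns mirror the fabrication-report tables, Tmax as a fraction).
#' @export
characterization_report <- function(est) {
  if (inherits(est, "filter_bank")) {
    wl <- wavelengths(est$grid)
    Tm <- t(vapply(est$bands, function(b) b$values, numeric(est$grid$n)))
    nm <- est$names
  } else if (inherits(est, "estimated_bank")) {
    wl <- est$wavelengths
    Tm <- est$transmissions
    nm <- est$band_names
  } else stop("characterization_report: unsupported input")
  rows <- lapply(seq_len(nrow(Tm)), function(i) {
    v <- Tm[i, ]
    keep <- !is.na(v)
    if (sum(keep) < 3) stop("characterization_report: band support too small")
    w <- wl[keep]; y <- v[keep]
    tmax <- max(y)
    peaks <- which(abs(y - tmax) < 1e-12)
    if (length(peaks) > 1) {
      warning(sprintf("characterization_report: plateau/tied maximum in band %s; lower wavelength chosen", nm[i]))
    }
    data.frame(band = nm[i], centering = w[peaks[1]],
               fwhm = fwhm_from_curve(w, y), tmax = tmax)
  })
  do.call(rbind, rows)
}
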