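# Forward model of the filter/sensor/illuminant imaging chain.
#
# Band response of the camera to sample k through filter i:
#   O[i, k] = sum_lambda S(l) u_i(l) E(l) r_k(l) dl,
# i.e. rows of the system matrix A are S * u_i * E * dl on the common grid,
# and O = A %*% t(R). Measurement noise is additive white Gaussian with a
# global standard deviation mean(|O|)/SNR (SNR = 100 in the design study).

#' System matrix of the imaging chain
#'
#' Row i holds `qe * band_i * spd * step` on the common grid, so that
#' `A %*% r` is the vector of noiseless band responses to reflectance `r`
#' (rectangle-rule quadrature folded in).
#'
#' @param qe Sensor quantum-efficiency [spectrum_curve()] (kind `"qe"`).
#' @param bank A [filter_bank()].
#' @param illum An [illuminant()].
#' @return Matrix `n_bands x n_lambda`, non-negative entries.
#' @export
system_matrix <- function(qe, bank, illum) {
  stopifnot(inherits(qe, "spectrum_curve"), inherits(bank, "filter_bank"),
            inherits(illum, "illuminant"))
  grid <- bank$grid
  if (!grids_equal(qe$grid, grid) || !grids_equal(illum$spd$grid, grid)) {
    stop("system_matrix: qe, bank and illuminant must share one grid")
  }
  base <- qe$values * illum$spd$values * grid$step
  A <- t(vapply(bank$bands, function(b) b$values * base,
                numeric(grid$n)))
  rownames(A) <- bank$names
  A
}

#' Camera response set
#'
#' Applies the system matrix to every sample of a reflectance set and adds
#' the design noise model: additive Gaussian white noise with standard
#' deviation `mean(abs(O)) / snr` shared across channels. `snr = Inf` gives
#' the noiseless response; a given seed gives reproducible noise.
#'
#' @param A System matrix from [system_matrix()].
#' @param ds A [reflectance_set()] on the same grid.
#' @param snr Signal-to-noise ratio, > 0 (default 100) or `Inf`.
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `camera_response_set` with fields `responses`
#'   (`n_bands x K`), `snr`, `seed`, `noise_sd`.
#' @export
camera_response <- function(A, ds, snr = 100, seed = NULL) {
  stopifnot(is.matrix(A), inherits(ds, "reflectance_set"))
  if (ncol(A) != ds$grid$n) {
    stop("camera_response: system matrix columns must match grid points")
  }
  if (!is.numeric(snr) || snr <= 0) stop("camera_response: snr must be > 0")
  O <- A %*% t(ds$samples)
  noise_sd <- 0
  if (is.finite(snr)) {
    noise_sd <- mean(abs(O)) / snr
    if (!is.null(seed)) set.seed(as.integer(seed))
    O <- O + matrix(stats::rnorm(length(O), sd = noise_sd),
                    nrow(O), ncol(O))
  }
  structure(list(responses = O, snr = snr, seed = seed, noise_sd = noise_sd),
            class = "camera_response_set")
}

#' @export
print.camera_response_set <- function(x, ...) {
  cat(sprintf("<camera_response_set> %d bands x %d samples, snr = %s\n",
              nrow(x$responses), ncol(x$responses), format(x$snr)))
  invisible(x)
}

#' Per-band energy balance under an illuminant
#'
#' For each band response curve S_p the expected camera response to a
#' perfect diffuser is `rho_p = sum I(l) S_p(l) dl` (rectangle rule). The
#' balance factors `max(rho)/rho_p` are the per-band software gains that
#' equalize all channels under that illuminant.
#'
#' @param illum An [illuminant()].
#' @param band_responses List of [spectrum_curve()] (per-band spectral
#'   response of the hybrid sensor, e.g. `qe * u_i`), or a [filter_bank()]
#'   whose transmissions are taken as the responses.
#' @return An object of class `energy_balance_report` with fields `rho`,
#'   `illuminant_name`, `balance_factors` and `band_names`.
#' @export
energy_balance <- function(illum, band_responses) {
  stopifnot(inherits(illum, "illuminant"))
  if (inherits(band_responses, "filter_bank")) {
    band_names <- band_responses$names
    band_responses <- band_responses$bands
  } else {
    band_names <- sprintf("P%d", seq_along(band_responses))
  }
  stopifnot(is.list(band_responses), length(band_responses) >= 1)
  grid <- band_responses[[1]]$grid
  for (b in band_responses) {
    if (!grids_equal(b$grid, grid)) stop("energy_balance: bands must share one grid")
  }
  if (!grids_equal(illum$spd$grid, grid)) {
    stop("energy_balance: illuminant must share the band grid")
  }
  spd <- illum$spd$values
  rho <- vapply(band_responses,
                function(b) sum(spd * b$values) * grid$step, numeric(1))
  if (any(rho <= 0)) {
    stop("energy_balance: degenerate band with zero response under this illuminant")
  }
  structure(list(rho = rho, illuminant_name = illum$name,
                 balance_factors = max(rho) / rho, band_names = band_names),
            class = "energy_balance_report")
}

#' @export
print.energy_balance_report <- function(x, ...) {
  cat(sprintf("<energy_balance_report> illuminant %s\n", x$illuminant_name))
  print(data.frame(band = x$band_names, rho = x$rho,
                   factor = x$balance_factors))
  invisible(x)
}

#' Write an energy-balance report to CSV
#' @param report An `energy_balance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_balance_csv <- function(report, path) {
  stopifnot(inherits(report, "energy_balance_report"))
  utils::write.csv(data.frame(band = report$band_names, rho = report$rho,
                              factor = report$balance_factors),
                   path, row.names = FALSE)
  invisible(path)
}
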