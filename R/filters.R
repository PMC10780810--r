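# Gaussian interference-filter transmission model and the measured VIS/NIR
# filter banks of the fabricated dual-camera prototype.
#
# Each band is modeled as a peak-normalized Gaussian
#   u(lambda) = alpha * exp(-(lambda - mu)^2 / (2 sigma^2)),
# sigma = FWHM / (2 sqrt(2 ln 2)). alpha is the peak transmission Tmax, the
# quantity fabrication is specified against (Tmax > 40%), which is why the
# model is peak-normalized rather than a unit-area density.

#' Gaussian width parameter from full width at half maximum
#'
#' @param fwhm Full width at half maximum (nm), > 0.
#' @return Standard deviation `fwhm / (2 sqrt(2 ln 2))` (nm).
#' @examples
#' sigma_from_fwhm(30)  # 12.7386...
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (!is.numeric(fwhm) || any(fwhm <= 0)) {
    stop("sigma_from_fwhm: fwhm must be > 0")
  }
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Gaussian filter specification
#'
#' @param center Center wavelength mu (nm).
#' @param fwhm Full width at half maximum (nm), > 0.
#' @param peak Peak transmission alpha in (0, 1].
#' @return An object of class `gaussian_filter_spec`.
#' @export
gaussian_filter_spec <- function(center, fwhm, peak = 1) {
  if (!is.numeric(fwhm) || fwhm <= 0) stop("gaussian_filter_spec: fwhm must be > 0")
  if (!is.numeric(peak) || peak <= 0 || peak > 1) {
    stop("gaussian_filter_spec: peak must lie in (0, 1]")
  }
  structure(list(center = center, fwhm = fwhm, peak = peak,
                 sigma = sigma_from_fwhm(fwhm)),
            class = "gaussian_filter_spec")
}

#' Gaussian transmission curve on a grid
#'
#' @param spec A [gaussian_filter_spec()].
#' @param grid A [wl_grid()].
#' @return A [spectrum_curve()] of kind `"transmission"`: symmetric about
#'   the center, equal to `peak` at the center when it lies on the grid.
#' @export
gaussian_transmission <- function(spec, grid) {
  stopifnot(inherits(spec, "gaussian_filter_spec"), inherits(grid, "wl_grid"))
  wl <- wavelengths(grid)
  u <- spec$peak * exp(-((wl - spec$center)^2) / (2 * spec$sigma^2))
  spectrum_curve(grid, u, kind = "transmission")
}

#' Filter bank
#'
#' An ordered set of per-band transmission curves on a shared grid.
#'
#' @param grid A [wl_grid()].
#' @param bands List of [spectrum_curve()] of kind `"transmission"`, all on
#'   `grid`.
#' @param names Per-band identifiers (default `P1`, `P2`, ...).
#' @return An object of class `filter_bank`.
#' @export
filter_bank <- function(grid, bands, names = NULL) {
  stopifnot(inherits(grid, "wl_grid"), is.list(bands), length(bands) >= 1)
  for (b in bands) {
    stopifnot(inherits(b, "spectrum_curve"))
    if (b$kind != "transmission") stop("filter_bank: bands must be transmissions")
    if (!grids_equal(b$grid, grid)) stop("filter_bank: bands must share the grid")
  }
  if (is.null(names)) names <- sprintf("P%d", seq_along(bands))
  if (length(names) != length(bands)) stop("filter_bank: one name per band")
  structure(list(grid = grid, bands = bands, names = as.character(names)),
            class = "filter_bank")
}

#' Build a filter bank from Gaussian specifications
#'
#' @param centers Center wavelengths (nm).
#' @param fwhm Scalar or per-band FWHM (nm).
#' @param peak Scalar or per-band peak transmission.
#' @param grid A [wl_grid()].
#' @param names Optional band names.
#' @return A [filter_bank()].
#' @export
gaussian_bank <- function(centers, fwhm = 30, peak = 1, grid = wl_grid(),
                          names = NULL) {
  n <- length(centers)
  fwhm <- rep_len(fwhm, n)
  peak <- rep_len(peak, n)
  bands <- lapply(seq_len(n), function(i) {
    gaussian_transmission(gaussian_filter_spec(centers[i], fwhm[i], peak[i]), grid)
  })
  filter_bank(grid, bands, names)
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d bands on %g-%g nm step %g\n",
              length(x$bands), x$grid$start, x$grid$stop, x$grid$step))
  invisible(x)
}

#' Number of bands in a filter bank
#' @param bank A [filter_bank()].
#' @return Integer band count.
#' @export
n_bands <- function(bank) length(bank$bands)

# Measured characteristics of the fabricated VIS and NIR 8-band MSFAs:
# per band, (specified center, measured center, measured FWHM, measured
# Tmax %). Full measured curves are not available in tabular form, so the
# banks are modeled as Gaussians from these measured parameters.
.msfa_vis_table <- data.frame(
  band = sprintf("P%d", 1:8),
  spec_center = c(421, 457, 493, 529, 565, 601, 637, 673),
  center      = c(425, 460, 500, 510, 560, 590, 630, 660),
  fwhm        = c(71, 52, 44, 39, 36, 34, 33, 33),
  tmax_pct    = c(41, 48, 53, 57, 62, 62, 63, 63)
)

.msfa_nir_table <- data.frame(
  band = sprintf("P%d", 1:8),
  spec_center = c(688, 718, 748, 778, 808, 838, 868, 898),
  center      = c(670, 705, 735, 760, 810, 840, 860, 885),
  fwhm        = c(31, 30, 30, 29, 30, 28, 27, 27),
  tmax_pct    = c(55, 53, 53, 52, 51, 49, 49, 47)
)

#' Measured filter-bank characteristics table
#'
#' Per-band specified center, measured center, measured FWHM and measured
#' peak transmission (%) for the fabricated VIS or NIR MSFA prototype.
#'
#' @param which `"VIS"` or `"NIR"`.
#' @return A data.frame with columns `band`, `spec_center`, `center`,
#'   `fwhm`, `tmax_pct`.
#' @export
measured_bank_table <- function(which = c("VIS", "NIR")) {
  which <- match.arg(which)
  if (which == "VIS") .msfa_vis_table else .msfa_nir_table
}

#' Measured VIS/NIR filter banks
#'
#' Gaussian-shaped banks built from the measured (center, FWHM, Tmax)
#' parameters of the fabricated 8-band VIS (425-660 nm) and NIR
#' (670-885 nm) MSFA prototypes.
#'
#' @param which `"VIS"` or `"NIR"`.
#' @param grid A [wl_grid()]; default full modeling grid.
#' @return A [filter_bank()] with 8 bands named `P1`...`P8`.
#' @export
measured_bank <- function(which = c("VIS", "NIR"), grid = wl_grid()) {
  tab <- measured_bank_table(which)
  gaussian_bank(tab$center, fwhm = tab$fwhm, peak = tab$tmax_pct / 100,
                grid = grid, names = tab$band)
}

#' Write a filter bank to CSV
#'
#' Same dialect as [write_spectra_csv()]: `wavelength_nm` column plus one
#' column per band.
#'
#' @param bank A [filter_bank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bank_csv <- function(bank, path) {
  stopifnot(inherits(bank, "filter_bank"))
  df <- data.frame(wavelength_nm = wavelengths(bank$grid))
  for (i in seq_along(bank$bands)) df[[bank$names[i]]] <- bank$bands[[i]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a filter bank from CSV
#' @param path CSV path in the [write_bank_csv()] dialect.
#' @return A [filter_bank()].
#' @export
read_bank_csv <- function(path) {
  ds <- read_spectra_csv(path, kind = "transmission")
  bands <- lapply(seq_len(nrow(ds$samples)), function(i) {
    spectrum_curve(ds$grid, ds$samples[i, ], kind = "transmission")
  })
  filter_bank(ds$grid, bands, names = ds$labels)
}
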