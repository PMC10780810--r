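# Wavelength grids and spectral curve containers shared by every module.
# All spectra are resampled onto a common grid before any matrix algebra;
# spectral integrals use the rectangle rule with weight delta-lambda.

#' Regular wavelength grid
#'
#' A closed, regularly spaced wavelength interval in nanometres. Every
#' spectral object in the package lives on such a grid, and all curves are
#' brought onto a common grid before any matrix operation.
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm), inclusive.
#' @param step Grid spacing (nm); `(stop - start)` must be an integer
#'   multiple of `step`.
#' @return An object of class `wl_grid` with fields `start`, `stop`, `step`
#'   and `n` (number of points, `(stop - start)/step + 1`).
#' @examples
#' g <- wl_grid(380, 1000, 1)
#' g$n  # 621
#' @export
wl_grid <- function(start = 380, stop = 1000, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) stop("wl_grid: start must be < stop")
  if (!(step > 0)) stop("wl_grid: step must be > 0")
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9) {
    stop("wl_grid: (stop - start) must be divisible by step")
  }
  structure(
    list(start = start, stop = stop, step = step, n = as.integer(round(k)) + 1L),
    class = "wl_grid"
  )
}

#' Wavelengths of a grid
#' @param grid A [wl_grid()].
#' @return Numeric vector of wavelengths (nm), inclusive of both endpoints.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  grid$start + grid$step * (seq_len(grid$n) - 1)
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start, x$stop, x$step, x$n))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(c(a$start, a$stop, a$step), c(b$start, b$stop, b$step),
                   tolerance = 1e-9))
}

#' Spectral curve on a wavelength grid
#'
#' @param grid A [wl_grid()].
#' @param values Non-negative numeric vector, one value per grid point.
#' @param kind One of `"reflectance"`, `"transmission"`, `"spd"`, `"qe"`.
#'   Reflectance and transmission curves are additionally required to stay
#'   below `1 + tol`.
#' @param tol Upper-bound tolerance for reflectance/transmission.
#' @return An object of class `spectrum_curve`.
#' @export
spectrum_curve <- function(grid, values,
                           kind = c("reflectance", "transmission", "spd", "qe"),
                           tol = 1e-6) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "wl_grid"), is.numeric(values))
  values <- as.numeric(values)
  if (length(values) != grid$n) {
    stop(sprintf("spectrum_curve: expected %d values, got %d",
                 grid$n, length(values)))
  }
  if (any(!is.finite(values))) stop("spectrum_curve: non-finite values")
  if (any(values < -tol)) stop("spectrum_curve: negative values")
  values <- pmax(values, 0)
  if (kind %in% c("reflectance", "transmission") && any(values > 1 + tol)) {
    stop(sprintf("spectrum_curve: %s values exceed 1 + tol", kind))
  }
  structure(list(grid = grid, values = values, kind = kind),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("<spectrum_curve:%s> %g-%g nm step %g (%d pts), range [%.4g, %.4g]\n",
              x$kind, x$grid$start, x$grid$stop, x$grid$step, x$grid$n,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Resample a spectrum onto another grid
#'
#' Linear interpolation onto the target grid points. Extrapolation is
#' refused: the target range must lie inside the source range.
#'
#' @param s A [spectrum_curve()].
#' @param target A [wl_grid()] contained in the source range.
#' @return A `spectrum_curve` of the same kind on `target`.
#' @export
resample <- function(s, target) {
  stopifnot(inherits(s, "spectrum_curve"), inherits(target, "wl_grid"))
  if (target$start < s$grid$start - 1e-9 || target$stop > s$grid$stop + 1e-9) {
    stop(sprintf(
      "resample: target range [%g, %g] exceeds source range [%g, %g]",
      target$start, target$stop, s$grid$start, s$grid$stop))
  }
  if (grids_equal(s$grid, target)) {
    return(spectrum_curve(target, s$values, s$kind))
  }
  y <- stats::approx(wavelengths(s$grid), s$values, xout = wavelengths(target),
                     method = "linear", rule = 1)$y
  spectrum_curve(target, y, s$kind, tol = 1e-6)
}

#' Reflectance dataset
#'
#' A matrix of sample reflectances (rows) on a common grid, with a species
#' label per sample. This is the container for the spectral library driving
#' band selection and Wiener estimation.
#'
#' @param grid A [wl_grid()].
#' @param samples Numeric matrix, K samples x n wavelengths, values in [0, 1].
#' @param labels Character/factor vector of length K (species per sample).
#' @return An object of class `reflectance_set`.
#' @export
reflectance_set <- function(grid, samples, labels = NULL) {
  stopifnot(inherits(grid, "wl_grid"))
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("reflectance_set: need at least one sample")
  if (ncol(samples) != grid$n) {
    stop(sprintf("reflectance_set: %d columns but grid has %d points",
                 ncol(samples), grid$n))
  }
  if (any(!is.finite(samples))) stop("reflectance_set: non-finite values")
  if (any(samples < -1e-6) || any(samples > 1 + 1e-6)) {
    stop("reflectance_set: reflectances must lie in [0, 1]")
  }
  samples <- pmin(pmax(samples, 0), 1)
  if (is.null(labels)) labels <- sprintf("s%03d", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples)) {
    stop("reflectance_set: one label per sample required")
  }
  structure(list(grid = grid, samples = samples, labels = as.character(labels)),
            class = "reflectance_set")
}

#' @export
print.reflectance_set <- function(x, ...) {
  cat(sprintf("<reflectance_set> %d samples x %d wavelengths (%g-%g nm), %d species\n",
              nrow(x$samples), x$grid$n, x$grid$start, x$grid$stop,
              length(unique(x$labels))))
  invisible(x)
}

#' Number of samples in a reflectance set
#' @param ds A [reflectance_set()].
#' @return Integer sample count.
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' Write spectra to CSV
#'
#' CSV dialect used throughout: UTF-8, comma separated, first column
#' `wavelength_nm`, one column per sample/curve with the label as header.
#'
#' @param ds A [reflectance_set()] (or a `filter_bank`, see
#'   [write_bank_csv()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "reflectance_set"))
  df <- data.frame(wavelength_nm = wavelengths(ds$grid),
                   t(ds$samples), check.names = FALSE)
  names(df) <- c("wavelength_nm", ds$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Inverse of [write_spectra_csv()]. The wavelength column must be strictly
#' increasing and regularly spaced; remaining columns are one sample each.
#'
#' @param path CSV file path.
#' @param kind Spectrum kind used for validation (default reflectance).
#' @return A [reflectance_set()].
#' @export
read_spectra_csv <- function(path, kind = "reflectance") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("read_spectra_csv: need wavelength column + >=1 sample")
  wl <- df[[1]]
  if (any(is.na(wl)) || any(diff(wl) <= 0)) {
    stop("read_spectra_csv: wavelengths must be strictly increasing")
  }
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-6) {
    stop("read_spectra_csv: wavelengths must be regularly spaced")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m))) stop("read_spectra_csv: ragged or non-numeric columns")
  grid <- wl_grid(wl[1], wl[length(wl)], steps[1])
  reflectance_set(grid, t(m), labels = colnames(df)[-1])
}

#' Illuminant
#'
#' A named spectral power distribution. See [standard_illuminant()] for the
#' shipped standard illuminants (A, D65, E, tungsten).
#'
#' @param name Identifier.
#' @param spd A [spectrum_curve()] of kind `"spd"`, not identically zero.
#' @return An object of class `illuminant`.
#' @export
illuminant <- function(name, spd) {
  stopifnot(is.character(name), inherits(spd, "spectrum_curve"))
  if (spd$kind != "spd") stop("illuminant: spd must have kind 'spd'")
  if (all(spd$values == 0)) stop("illuminant: spd is identically zero")
  structure(list(name = name, spd = spd), class = "illuminant")
}

#' @export
print.illuminant <- function(x, ...) {
  cat(sprintf("<illuminant> %s on %g-%g nm\n",
              x$name, x$spd$grid$start, x$spd$grid$stop))
  invisible(x)
}
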