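# Wiener (linear MMSE) reconstruction of reflectance spectra from a few
# band responses, r_hat = W O, with
#   W = C_r A' (A C_r A' + v I)^(-1),
# C_r the uncentered second-moment matrix of the training reflectances and
# v the measurement-noise variance. Evaluation metrics: per-sample RMS,
# goodness-of-fit coefficient (GFC) and CIEDE2000.

#' Fit a Wiener reflectance estimator
#'
#' @param A System matrix (`n_bands x n_lambda`) from [system_matrix()].
#' @param ds Training [reflectance_set()] on the same grid.
#' @param noise_variance Measurement noise variance (linear units squared),
#'   `>= 0`. Use `camera_response(...)$noise_sd^2` to match a simulated
#'   acquisition.
#' @return An object of class `wiener_estimator` with fields `W`
#'   (`n_lambda x n_bands`), `autocorrelation` (`C_r`), `noise_variance`,
#'   and `grid`.
#' @export
fit_wiener <- function(A, ds, noise_variance = 0) {
  stopifnot(is.matrix(A), inherits(ds, "reflectance_set"))
  if (ncol(A) != ds$grid$n) stop("fit_wiener: A columns must match grid points")
  if (!is.numeric(noise_variance) || noise_variance < 0) {
    stop("fit_wiener: noise_variance must be >= 0")
  }
  R <- ds$samples
  Cr <- crossprod(R) / nrow(R)           # (1/K) sum r r'
  ACr <- A %*% Cr                        # n_bands x n_lambda
  M <- ACr %*% t(A) + diag(noise_variance, nrow(A))
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    if (noise_variance == 0) {
      stop("fit_wiener: A C_r A' is singular at zero noise; ",
           "supply noise_variance > 0 to regularize")
    }
    stop("fit_wiener: normal matrix is not positive definite")
  }
  W <- t(chol2inv(ch) %*% ACr)           # n_lambda x n_bands
  structure(list(W = W, autocorrelation = Cr,
                 noise_variance = noise_variance, grid = ds$grid),
            class = "wiener_estimator")
}

#' @export
print.wiener_estimator <- function(x, ...) {
  cat(sprintf("<wiener_estimator> %d wavelengths x %d bands, noise variance %.3g\n",
              nrow(x$W), ncol(x$W), x$noise_variance))
  invisible(x)
}

#' Reconstruct reflectances from camera responses
#'
#' @param est A [fit_wiener()] estimator.
#' @param O A `camera_response_set` or a bare `n_bands x K` matrix.
#' @param clip Clip the estimates to [0, 1]? Off by default; the raw linear
#'   estimate is what the evaluation metrics are computed on.
#' @param labels Optional per-sample labels for the result.
#' @return A [reflectance_set()] of estimates (values clipped into [0, 1]
#'   for container validity only when `clip = TRUE`; otherwise returned as
#'   a plain matrix attribute-free container with kind checks relaxed).
#' @export
reconstruct <- function(est, O, clip = FALSE, labels = NULL) {
  stopifnot(inherits(est, "wiener_estimator"))
  if (inherits(O, "camera_response_set")) O <- O$responses
  if (!is.matrix(O)) O <- matrix(O, ncol = 1)
  if (nrow(O) != ncol(est$W)) {
    stop("reconstruct: response rows must match estimator bands")
  }
  Rhat <- t(est$W %*% O)                 # K x n_lambda
  if (clip) Rhat <- pmin(pmax(Rhat, 0), 1)
  structure(list(grid = est$grid, samples = Rhat,
                 labels = if (is.null(labels)) sprintf("s%03d", seq_len(nrow(Rhat)))
                          else as.character(labels)),
            class = "reflectance_set")
}

#' Root-mean-square spectral error
#' @param r,r_hat Numeric vectors of equal length.
#' @return `sqrt(mean((r - r_hat)^2))`.
#' @export
rms <- function(r, r_hat) {
  if (length(r) != length(r_hat)) stop("rms: length mismatch")
  sqrt(mean((r - r_hat)^2))
}

#' Goodness-of-fit coefficient
#'
#' Normalized absolute inner product `|<r, r_hat>| / (||r|| ||r_hat||)`;
#' 1 means the reconstruction is proportional to the truth.
#'
#' @param r,r_hat Non-zero numeric vectors of equal length.
#' @return Value in [0, 1].
#' @export
gfc <- function(r, r_hat) {
  if (length(r) != length(r_hat)) stop("gfc: length mismatch")
  nr <- sqrt(sum(r^2)); nh <- sqrt(sum(r_hat^2))
  if (nr == 0 || nh == 0) stop("gfc: zero vector")
  min(abs(sum(r * r_hat)) / (nr * nh), 1)
}

#' CIEDE2000 difference between a reflectance and its reconstruction
#'
#' Converts both spectra to CIE XYZ under `illum` with the 1931 2-degree
#' observer, then to CIELAB with the illuminant white point, and returns
#' the CIEDE2000 difference. Grids that only partially cover the 380-780 nm
#' observer support (e.g. the NIR camera) are evaluated on the overlapping
#' region; the result then carries attribute `partial_support = TRUE`.
#'
#' @param r,r_hat Numeric vectors on `grid` (or `reflectance_set`s; then
#'   the metric is computed row-wise and `grid` is taken from them).
#' @param illum An [illuminant()].
#' @param grid The common [wl_grid()] (required for bare vectors).
#' @return Numeric vector of colour differences (`>= 0`).
#' @export
delta_e2000 <- function(r, r_hat, illum, grid = NULL) {
  if (inherits(r, "reflectance_set")) {
    grid <- r$grid; m1 <- r$samples
  } else m1 <- matrix(r, nrow = 1)
  if (inherits(r_hat, "reflectance_set")) {
    if (is.null(grid)) grid <- r_hat$grid
    m2 <- r_hat$samples
  } else m2 <- matrix(r_hat, nrow = 1)
  if (is.null(grid)) stop("delta_e2000: grid required for bare vectors")
  if (nrow(m1) != nrow(m2) || ncol(m1) != ncol(m2)) {
    stop("delta_e2000: shape mismatch")
  }
  x1 <- reflectance_to_xyz(m1, grid, illum)
  x2 <- reflectance_to_xyz(m2, grid, illum)
  de <- ciede2000(xyz_to_lab(x1$xyz, x1$white), xyz_to_lab(x2$xyz, x2$white))
  attr(de, "partial_support") <- x1$partial
  de
}

#' Evaluate a reconstruction against the ground truth
#'
#' Computes per-sample RMS, GFC and CIEDE2000, their summary statistics
#' (min/max/mean/median/std) and the fractions of samples with GFC > 0.99
#' and GFC > 0.95.
#'
#' @param ds Ground-truth [reflectance_set()].
#' @param ds_hat Reconstructed set, same grid and sample count.
#' @param illum An [illuminant()] for the colour-difference stage.
#' @return An object of class `reconstruction_report` with fields `rms`,
#'   `gfc`, `delta_e2000` (per-sample vectors), `summary` (data.frame),
#'   `gfc_over_99`, `gfc_over_95`, `partial_cmf_support`.
#' @export
evaluate <- function(ds, ds_hat, illum = standard_illuminant("A", ds$grid)) {
  stopifnot(inherits(ds, "reflectance_set"), inherits(ds_hat, "reflectance_set"))
  if (nrow(ds$samples) != nrow(ds_hat$samples)) {
    stop("evaluate: mismatched sample counts")
  }
  if (!grids_equal(ds$grid, ds_hat$grid)) stop("evaluate: grids differ")
  K <- nrow(ds$samples)
  v_rms <- vapply(seq_len(K),
                  function(k) rms(ds$samples[k, ], ds_hat$samples[k, ]),
                  numeric(1))
  v_gfc <- vapply(seq_len(K),
                  function(k) gfc(ds$samples[k, ], ds_hat$samples[k, ]),
                  numeric(1))
  v_de <- delta_e2000(ds, ds_hat, illum)
  stat <- function(v) c(min = min(v), max = max(v), mean = mean(v),
                        median = stats::median(v),
                        std = if (K > 1) stats::sd(v) else 0)
  summ <- data.frame(rbind(rms = stat(v_rms), gfc = stat(v_gfc),
                           delta_e2000 = stat(as.numeric(v_de))))
  structure(list(rms = v_rms, gfc = v_gfc, delta_e2000 = as.numeric(v_de),
                 summary = summ,
                 gfc_over_99 = mean(v_gfc > 0.99),
                 gfc_over_95 = mean(v_gfc > 0.95),
                 partial_cmf_support = isTRUE(attr(v_de, "partial_support"))),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat("<reconstruction_report>\n")
  print(round(x$summary, 4))
  cat(sprintf("GFC > 0.99: %.1f%%   GFC > 0.95: %.1f%%\n",
              100 * x$gfc_over_99, 100 * x$gfc_over_95))
  if (x$partial_cmf_support) {
    cat("note: Delta E 2000 computed on partial 380-780 nm support\n")
  }
  invisible(x)
}

#' Export a reconstruction report as a summary-statistics CSV
#'
#' Row names mirror the headline simulation table of the design study
#' (`Min Delta E 2000` ... `GFC > 0.95`).
#'
#' @param report A `reconstruction_report`.
#' @param path Output path.
#' @return The exported data.frame, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "reconstruction_report"))
  s <- report$summary
  df <- data.frame(
    Parameter = c("Min Delta E 2000", "Max Delta E 2000", "Mean Delta E 2000",
                  "Median E 2000", "STD Delta E 2000",
                  "Min RMS", "Max RMS", "Mean RMS",
                  "GFC > 0.99", "GFC > 0.95"),
    Value = c(s["delta_e2000", "min"], s["delta_e2000", "max"],
              s["delta_e2000", "mean"], s["delta_e2000", "median"],
              s["delta_e2000", "std"],
              s["rms", "min"], s["rms", "max"], s["rms", "mean"],
              report$gfc_over_99, report$gfc_over_95)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
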