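# Colorimetric pathway for the Delta E 2000 metric:
# reflectance -> CIE XYZ (1931 2-degree observer) -> CIELAB -> CIEDE2000.
#
# The colour-matching functions use the published multi-lobe Gaussian
# analytic fit of the 1931 2-degree observer (piecewise Gaussians with
# separate left/right widths). No pre-installed package tabulates the CMFs
# and re-typing 81 rows x 3 curves invites silent transcription errors; the
# analytic fit is accurate to a few percent of peak, ample for a relative
# reconstruction-quality metric. The CIEDE2000 formula itself is exact and
# verified against the full published 34-pair verification set.

# piecewise Gaussian with separate left/right standard deviations
pw_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-((x - mu)^2) / (2 * s^2))
}

#' CIE 1931 2-degree colour-matching functions (analytic fit)
#'
#' @param wl Numeric vector of wavelengths (nm).
#' @return Matrix with columns `x`, `y`, `z`; zero outside roughly
#'   380-780 nm support.
#' @export
cie1931_cmf <- function(wl) {
  x <- 1.056 * pw_gauss(wl, 599.8, 37.9, 31.0) +
       0.362 * pw_gauss(wl, 442.0, 16.0, 26.7) -
       0.065 * pw_gauss(wl, 501.1, 20.4, 26.2)
  y <- 0.821 * pw_gauss(wl, 568.8, 46.9, 40.5) +
       0.286 * pw_gauss(wl, 530.9, 16.3, 31.1)
  z <- 1.217 * pw_gauss(wl, 437.0, 11.8, 36.0) +
       0.681 * pw_gauss(wl, 459.0, 26.0, 13.8)
  cbind(x = pmax(x, 0), y = pmax(y, 0), z = pmax(z, 0))
}

# Integrate reflectance rows to XYZ under an illuminant, restricted to the
# CMF support (380-780 nm). Returns list(xyz = K x 3, white = length-3,
# partial = logical) where partial flags grids that only partly cover the
# support.
reflectance_to_xyz <- function(samples, grid, illum) {
  wl <- wavelengths(grid)
  support <- wl >= 380 & wl <= 780
  if (!any(support)) {
    stop("delta_e2000: grid does not overlap the 380-780 nm CMF support")
  }
  partial <- grid$start > 380 + 1e-9 || grid$stop < 780 - 1e-9
  wl_s <- wl[support]
  cmf <- cie1931_cmf(wl_s)
  spd <- resample(illum$spd, grid)$values[support]
  k <- 100 / sum(spd * cmf[, "y"] * grid$step)
  m <- samples[, support, drop = FALSE]
  xyz <- k * grid$step * (m %*% (cmf * spd))
  white <- k * grid$step * colSums(cmf * spd)
  list(xyz = xyz, white = white, partial = partial)
}

#' Convert CIE XYZ to CIELAB
#'
#' @param xyz Matrix (K x 3) or length-3 vector of tristimulus values.
#' @param white Reference white tristimulus vector (Xn, Yn, Zn).
#' @return Matrix K x 3 of (L*, a*, b*).
#' @export
xyz_to_lab <- function(xyz, white) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  t_ <- sweep(xyz, 2, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(t_ > eps, t_^(1 / 3), t_ / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' CIEDE2000 colour difference between CIELAB pairs
#'
#' Implements the CIEDE2000 formula (kL = kC = kH = 1), including the
#' published hue-rotation and weighting terms. Vectorized over rows.
#'
#' @param lab1,lab2 Matrices (K x 3) or length-3 vectors of (L*, a*, b*).
#' @return Numeric vector of colour differences.
#' @export
ciede2000 <- function(lab1, lab2) {
  if (is.null(dim(lab1))) lab1 <- matrix(lab1, nrow = 1)
  if (is.null(dim(lab2))) lab2 <- matrix(lab2, nrow = 1)
  stopifnot(nrow(lab1) == nrow(lab2))
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]

  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)

  hp <- function(a, b) {
    h <- atan2(b, a) * 180 / pi
    h <- ifelse(h < 0, h + 360, h)
    ifelse(a == 0 & b == 0, 0, h)
  }
  h1p <- hp(a1p, b1); h2p <- hp(a2p, b2)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(dh) <= 180, dh,
         ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  T_ <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
            0.24 * cos(2 * hbp * pi / 180) +
            0.32 * cos((3 * hbp + 6) * pi / 180) -
            0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T_
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}
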