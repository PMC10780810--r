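test_that("Wiener estimator: invertible limit, infinite-noise limit, longhand oracle", {
  set.seed(2)
  g <- wl_grid(500, 540, 10)  # 5 wavelengths
  R <- matrix(runif(40, 0.1, 0.9), 8, 5)
  ds <- reflectance_set(g, R)

  # square invertible A, zero noise, full-rank C_r -> W = A^-1
  A <- diag(5) + matrix(runif(25, 0, 0.2), 5)
  est <- fit_wiener(A, ds, 0)
  expect_equal(est$W, solve(A), tolerance = 1e-8, ignore_attr = TRUE)

  # huge noise shrinks W toward zero
  est_inf <- fit_wiener(A, ds, 1e12)
  expect_lt(max(abs(est_inf$W)), 1e-6)

  # 5-wavelength 2-band toy vs the explicit normal-equation formula
  A2 <- matrix(runif(10), 2, 5)
  v <- 0.01
  est2 <- fit_wiener(A2, ds, v)
  Cr <- t(R) %*% R / nrow(R)
  W_longhand <- Cr %*% t(A2) %*% solve(A2 %*% Cr %*% t(A2) + v * diag(2))
  expect_equal(est2$W, W_longhand, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(isSymmetric(est2$autocorrelation, tol = 1e-12))
})

test_that("Wiener estimator errors: singular zero-noise system advises regularization", {
  g <- wl_grid(500, 540, 10)
  ds <- reflectance_set(g, matrix(rep(0.5, 5), 1))  # rank-1 C_r
  A <- matrix(1, 2, 5)                              # duplicated band
  expect_error(fit_wiener(A, ds, 0), "noise_variance")
  expect_error(fit_wiener(A, ds, -1), "noise_variance")
})

test_that("reconstruct: round trip, linearity, longhand product", {
  set.seed(3)
  g <- wl_grid(500, 540, 10)
  R <- matrix(runif(40, 0.1, 0.9), 8, 5)
  ds <- reflectance_set(g, R)
  A <- diag(5) + matrix(runif(25, 0, 0.2), 5)
  est <- fit_wiener(A, ds, 0)
  O <- camera_response(A, ds, snr = Inf)
  expect_equal(reconstruct(est, O)$samples, R, tolerance = 1e-6,
               ignore_attr = TRUE)

  zero <- reconstruct(est, matrix(0, 5, 3))
  expect_true(all(zero$samples == 0))

  W <- est$W; Otoy <- matrix(runif(10), 5, 2)
  expect_equal(reconstruct(est, Otoy)$samples, t(W %*% Otoy),
               ignore_attr = TRUE)
  expect_error(reconstruct(est, matrix(0, 3, 2)), "bands")
})

test_that("nested filter banks never increase zero-noise training MSE", {
  set.seed(4)
  g <- wl_grid(420, 660, 20)  # 13 wavelengths
  ds <- gen_reflectance_set(veg_params(n_samples = 30, n_species = 3,
                                       seed = 9, noise_std = 0.02),
                            g)
  qe <- gen_sensor_qe(g)
  il <- flat_illuminant(g)
  mse <- function(centers) {
    bank <- gaussian_bank(centers, fwhm = 40, grid = g)
    A <- system_matrix(qe, bank, il)
    est <- fit_wiener(A, ds, 1e-12)
    O <- camera_response(A, ds, snr = Inf)
    mean((reconstruct(est, O)$samples - ds$samples)^2)
  }
  small <- c(480, 560)
  for (extra in list(620, c(440, 620), c(440, 520, 620))) {
    expect_lte(mse(c(small, extra)), mse(small) + 1e-12)
  }
})

test_that("rms: identity, handmade case, constant offset", {
  expect_equal(rms(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rms(c(0, 0), c(0.1, -0.1)), 0.1)
  for (n in c(3, 10, 31)) {
    expect_equal(rms(rep(0.4, n), rep(0.4 + 0.07, n)), 0.07, tolerance = 1e-12)
  }
  expect_error(rms(1:3, 1:4), "length")
})

test_that("gfc: scale invariance, orthogonality, handmade value", {
  r <- runif(20)
  expect_equal(gfc(r, 3 * r), 1, tolerance = 1e-12)
  expect_equal(gfc(c(1, 0), c(0, 1)), 0)
  expect_equal(gfc(c(1, 0, 1), c(1, 1, 0)), 0.5, tolerance = 1e-12)
  expect_error(gfc(c(0, 0), c(1, 1)), "zero")
})

test_that("rms and gfc are permutation-equivariant over samples", {
  set.seed(5)
  R <- matrix(runif(50), 5); Rh <- R + matrix(rnorm(50, sd = 0.02), 5)
  per_rms <- sapply(1:5, function(k) rms(R[k, ], Rh[k, ]))
  per_gfc <- sapply(1:5, function(k) gfc(R[k, ], Rh[k, ]))
  p <- sample(5)
  expect_equal(sapply(p, function(k) rms(R[k, ], Rh[k, ])), per_rms[p])
  expect_equal(sapply(p, function(k) gfc(R[k, ], Rh[k, ])), per_gfc[p])
})

test_that("ciede2000 reproduces the full published verification set", {
  cases <- ciede2000_cases()
  got <- ciede2000(cases$lab1, cases$lab2)
  expect_equal(got, cases$de, tolerance = 1e-4)
  # symmetry on the same set
  expect_equal(ciede2000(cases$lab2, cases$lab1), got, tolerance = 1e-12)
})

test_that("delta_e2000 spectral pathway: identity, symmetry, partial support", {
  g <- wl_grid(380, 780, 5)
  ds <- gen_reflectance_set(veg_params(n_samples = 4, n_species = 2, seed = 2),
                            g)
  il <- standard_illuminant("A", g)
  expect_equal(as.numeric(delta_e2000(ds, ds, il)), rep(0, 4))

  other <- reflectance_set(g, pmin(ds$samples + 0.05, 1), ds$labels)
  d1 <- delta_e2000(ds, other, il)
  d2 <- delta_e2000(other, ds, il)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
  expect_false(attr(d1, "partial_support"))

  # NIR-style grid: only partial CMF overlap, flagged
  gn <- wl_grid(650, 1000, 5)
  dn <- gen_reflectance_set(veg_params(n_samples = 2, n_species = 1, seed = 2),
                            gn)
  dd <- delta_e2000(dn, dn, standard_illuminant("A", gn))
  expect_true(attr(dd, "partial_support"))
  gx <- wl_grid(800, 1000, 5)
  dx <- gen_reflectance_set(veg_params(n_samples = 2, n_species = 1, seed = 2), gx)
  expect_error(delta_e2000(dx, dx, standard_illuminant("A", gx)), "support")
})

test_that("evaluate: perfect reconstruction, degenerate statistics, spreadsheet oracle", {
  g <- wl_grid(380, 780, 10)
  ds <- gen_reflectance_set(veg_params(n_samples = 3, n_species = 2, seed = 6),
                            g)
  il <- standard_illuminant("A", g)
  perfect <- evaluate(ds, ds, il)
  expect_equal(perfect$summary["rms", ], perfect$summary["rms", ] * 0)
  expect_equal(perfect$gfc_over_99, 1)
  expect_equal(perfect$gfc_over_95, 1)

  one <- reflectance_set(g, ds$samples[1, , drop = FALSE])
  hat <- reflectance_set(g, pmin(one$samples + 0.02, 1))
  r1 <- evaluate(one, hat, il)
  expect_equal(r1$summary["rms", "min"], r1$summary["rms", "max"])
  expect_equal(r1$summary["rms", "std"], 0)

  hat3 <- reflectance_set(g, pmin(ds$samples +
                                  matrix(c(0.01, 0.02, 0.03), 3, g$n), 1))
  r3 <- evaluate(ds, hat3, il)
  per <- sapply(1:3, function(k) rms(ds$samples[k, ], hat3$samples[k, ]))
  expect_equal(r3$summary["rms", "mean"], mean(per), tolerance = 1e-12)
  expect_equal(r3$summary["rms", "median"], median(per), tolerance = 1e-12)
  expect_equal(r3$summary["rms", "std"], sd(per), tolerance = 1e-12)
  expect_error(evaluate(ds, one, il), "sample")
})

test_that("report CSV mirrors the headline table row names", {
  g <- wl_grid(380, 780, 10)
  ds <- gen_reflectance_set(veg_params(n_samples = 3, n_species = 2, seed = 6), g)
  rep_ <- evaluate(ds, ds, standard_illuminant("A", g))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_report_csv(rep_, path)
  expect_identical(df$Parameter,
                   c("Min Delta E 2000", "Max Delta E 2000",
                     "Mean Delta E 2000", "Median E 2000",
                     "STD Delta E 2000", "Min RMS", "Max RMS", "Mean RMS",
                     "GFC > 0.99", "GFC > 0.95"))
  expect_true(file.exists(path))
})
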