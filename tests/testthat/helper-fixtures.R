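# Shared fixtures and independent oracles for the test suite.

# small coarse grid for fast forward-model tests
tiny_grid <- function() wl_grid(400, 700, 10)

# small seeded vegetation library on the coarse grid
tiny_dataset <- function(n = 40, seed = 3) {
  gen_reflectance_set(veg_params(n_samples = n, n_species = 4, seed = seed),
                      tiny_grid())
}

flat_illuminant <- function(grid) standard_illuminant("E", grid)

# peak signal-to-noise ratio in dB for signals on a [0, 1]-ish scale
psnr_db <- function(truth, est) {
  mse <- mean((truth - est)^2)
  10 * log10(max(truth)^2 / mse)
}

# Straight-loop brute-force oracle for the two-pass bilinear demosaicking
# rule, written independently of the package implementation: explicit
# neighbour scans, no approx()/vectorization.
oracle_line_fill <- function(vals_at, n) {
  # vals_at: named-by-position numeric (NA where unknown)
  pos <- which(!is.na(vals_at))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i %in% pos) { out[i] <- vals_at[i]; next }
    left <- pos[pos < i]; right <- pos[pos > i]
    if (length(left) && length(right)) {
      l <- max(left); r <- min(right)
      out[i] <- vals_at[l] + (vals_at[r] - vals_at[l]) * (i - l) / (r - l)
    } else if (length(left)) {
      out[i] <- vals_at[max(left)]
    } else {
      out[i] <- vals_at[min(right)]
    }
  }
  out
}

oracle_demosaic <- function(raw, layout) {
  raw <- unclass(raw)
  h <- nrow(raw); w <- ncol(raw)
  nb <- layout$n_bands
  pat <- layout$pattern
  cube <- array(NA_real_, c(h, w, nb))
  for (b in 0:(nb - 1)) {
    samp <- matrix(FALSE, h, w)
    for (y in 1:h) for (x in 1:w) {
      samp[y, x] <- pat[(y - 1) %% 4 + 1, (x - 1) %% 4 + 1] == b
    }
    # pass A: rows that contain samples, then complete down columns
    pa <- matrix(NA_real_, h, w)
    for (y in 1:h) {
      if (any(samp[y, ])) {
        line <- rep(NA_real_, w); line[samp[y, ]] <- raw[y, samp[y, ]]
        pa[y, ] <- oracle_line_fill(line, w)
      }
    }
    for (x in 1:w) {
      col <- pa[, x]
      pa[, x] <- oracle_line_fill(col, h)
    }
    # pass B: columns first, then complete along rows
    pb <- matrix(NA_real_, h, w)
    for (x in 1:w) {
      if (any(samp[, x])) {
        line <- rep(NA_real_, h); line[samp[, x]] <- raw[samp[, x], x]
        pb[, x] <- oracle_line_fill(line, h)
      }
    }
    for (y in 1:h) {
      pb[y, ] <- oracle_line_fill(pb[y, ], w)
    }
    plane <- (pa + pb) / 2
    plane[samp] <- raw[samp]
    cube[, , b + 1] <- plane
  }
  cube
}

# Published CIEDE2000 verification set (34 Lab pairs with reference
# differences), cross-checked against an independent implementation.
ciede2000_cases <- function() {
  lab1 <- matrix(c(
    50,2.6772,-79.7751,  50,3.1571,-77.2803,  50,2.8361,-74.02,
    50,-1.3802,-84.2814, 50,-1.1848,-84.8006, 50,-0.9009,-85.5211,
    50,0,0,              50,-1,2,             50,2.49,-0.001,
    50,2.49,-0.001,      50,2.49,-0.001,      50,2.49,-0.001,
    50,-0.001,2.49,      50,-0.001,2.49,      50,-0.001,2.49,
    50,2.5,0,            50,2.5,0,            50,2.5,0,
    50,2.5,0,            50,2.5,0,            50,2.5,0,
    50,2.5,0,            50,2.5,0,            50,2.5,0,
    60.2574,-34.0099,36.2677, 63.0109,-31.0961,-5.8663,
    61.2901,3.7196,-5.3901,   35.0831,-44.1164,3.7933,
    22.7233,20.0904,-46.694,  36.4612,47.858,18.3852,
    90.8027,-2.0831,1.441,    90.9257,-0.5406,-0.9208,
    6.7747,-0.2908,-2.4247,   2.0776,0.0795,-1.135
  ), ncol = 3, byrow = TRUE)
  lab2 <- matrix(c(
    50,0,-82.7485, 50,0,-82.7485, 50,0,-82.7485,
    50,0,-82.7485, 50,0,-82.7485, 50,0,-82.7485,
    50,-1,2,       50,0,0,        50,-2.49,0.0009,
    50,-2.49,0.001, 50,-2.49,0.0011, 50,-2.49,0.0012,
    50,0.0009,-2.49, 50,0.001,-2.49, 50,0.0011,-2.49,
    50,0,-2.5,     73,25,-18,     61,-5,29,
    56,-27,-3,     58,24,15,      50,3.1736,0.5854,
    50,3.2972,0,   50,1.8634,0.5757, 50,3.2592,0.335,
    60.4626,-34.1751,39.4387, 62.8187,-29.7946,-4.0864,
    61.4292,2.248,-4.962,     35.0232,-40.0716,1.5901,
    23.0331,14.973,-42.5619,  36.2715,50.5065,21.2231,
    91.1528,-1.6435,0.0447,   88.6381,-0.8985,-0.7239,
    5.8714,-0.0985,-2.2286,   0.9033,-0.0636,-0.5514
  ), ncol = 3, byrow = TRUE)
  de <- c(2.0425, 2.8615, 3.4412, 1.0, 1.0, 1.0, 2.3669, 2.3669,
          7.1792, 7.1792, 7.2195, 7.2195, 4.8045, 4.8045, 4.7461,
          4.3065, 27.1492, 22.8977, 31.903, 19.4535, 1.0, 1.0, 1.0, 1.0,
          1.2644, 1.263, 1.8731, 1.8645, 2.0373, 1.4146, 1.4441,
          1.5381, 0.6377, 0.9082)
  list(lab1 = lab1, lab2 = lab2, de = de)
}

# numerically measure the FWHM of a sampled curve (independent of the
# package's characterization module: dense argmax + linear crossings)
measure_fwhm <- function(wl, v) {
  i <- which.max(v)
  half <- v[i] / 2
  l <- max(which(v[1:i] < half))
  xl <- wl[l] + (half - v[l]) / (v[l + 1] - v[l]) * (wl[l + 1] - wl[l])
  r <- i - 1 + min(which(v[i:length(v)] < half))
  xr <- wl[r - 1] + (v[r - 1] - half) / (v[r - 1] - v[r]) * (wl[r] - wl[r - 1])
  xr - xl
}
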