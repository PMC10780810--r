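# Moxel layouts, raw-mosaic simulation, bilinear demosaicking and
# Lambertian-white calibration.
#
# The moxel is the 4x4 repeating unit cell of the MSFA: 8 bands, two pixels
# per band. Coordinates are row-major, 0-based in the layout arithmetic
# (R matrices are 1-based; the moxel phase is anchored at the top-left
# pixel). Raw mosaics and cubes are plain numeric matrices / 3-D arrays;
# on disk they use text formats (ASCII PGM for 16-bit raws, one PGM page
# per band for cubes) because no binary-image package is available.

#' Moxel layout
#'
#' @param pattern 4x4 integer matrix of band indices in `0..n_bands-1`.
#' @param n_bands Number of bands (default 8).
#' @param strict Require exactly two pixels per band (the dual-camera
#'   default); with `strict = FALSE` any multiplicity pattern covering all
#'   bands is accepted (e.g. extra pixels for low-sensitivity NIR bands).
#' @return An object of class `moxel_layout` with fields `pattern`,
#'   `n_bands`, `multiplicity` (named per-band pixel counts).
#' @export
moxel_layout <- function(pattern, n_bands = 8, strict = TRUE) {
  pattern <- as.matrix(pattern)
  if (!all(dim(pattern) == c(4, 4))) stop("moxel_layout: pattern must be 4x4")
  dimnames(pattern) <- NULL
  storage.mode(pattern) <- "integer"
  if (any(pattern < 0L) || any(pattern >= n_bands)) {
    stop("moxel_layout: band indices must lie in 0..n_bands-1")
  }
  mult <- tabulate(pattern + 1L, nbins = n_bands)
  if (any(mult == 0L)) stop("moxel_layout: every band must appear in the pattern")
  if (strict && any(mult != 2L)) {
    stop("moxel_layout: default validation requires 2 pixels per band ",
         "(use strict = FALSE for unequal multiplicity)")
  }
  names(mult) <- as.character(seq_len(n_bands) - 1L)
  structure(list(pattern = pattern, n_bands = as.integer(n_bands),
                 multiplicity = mult),
            class = "moxel_layout")
}

#' Default dual-camera moxel layout
#'
#' 4x4 pattern with every band twice, duplicates offset by 2 rows and 2
#' columns for quasi-uniform spatial sampling. The VIS and NIR cameras
#' share the geometry and differ only in which filter bank the indices
#' refer to.
#'
#' @param which `"VIS"` or `"NIR"` (same geometry; kept for symmetry with
#'   the two physical cameras).
#' @return A [moxel_layout()].
#' @export
default_layout <- function(which = c("VIS", "NIR")) {
  which <- match.arg(which)
  moxel_layout(matrix(c(0L, 1L, 2L, 3L,
                        4L, 5L, 6L, 7L,
                        2L, 3L, 0L, 1L,
                        6L, 7L, 4L, 5L), 4, 4, byrow = TRUE))
}

#' Read / write a moxel layout as text
#'
#' Layout files are 4 lines of 4 whitespace-separated integers.
#'
#' @param path File path.
#' @param layout A [moxel_layout()] (for writing).
#' @param strict Passed to [moxel_layout()] when reading.
#' @return `read_layout` returns a [moxel_layout()]; `write_layout`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path, strict = TRUE) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  moxel_layout(m, n_bands = max(m) + 1L, strict = strict)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "moxel_layout"))
  utils::write.table(layout$pattern, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Moxel tiling counts
#'
#' Number of times the 4x4 mask repeats along lines and columns; for the
#' 1600x1200 sensor this is 300 x 400.
#'
#' @param height,width Image dimensions in pixels, each divisible by 4.
#' @param layout A [moxel_layout()] (its 4x4 period is what is tiled).
#' @return Named list `n_l` (line repeats, height/4) and `n_c` (column
#'   repeats, width/4).
#' @export
tile_counts <- function(height, width, layout = default_layout()) {
  if (height %% 4 != 0 || width %% 4 != 0) {
    stop("tile_counts: height and width must be divisible by 4")
  }
  list(n_l = as.integer(height / 4), n_c = as.integer(width / 4))
}

# band index (0-based) of every pixel of an H x W frame under the layout
band_map <- function(height, width, layout) {
  ri <- ((seq_len(height) - 1L) %% 4L) + 1L
  ci <- ((seq_len(width) - 1L) %% 4L) + 1L
  layout$pattern[ri, ci, drop = FALSE]
}

#' Mosaic a spectral cube into a raw single-channel image
#'
#' Forward simulator of the snapshot acquisition: each pixel keeps the
#' value of the band its filter selects,
#' `raw[y, x] = cube[y, x, pattern[y mod 4, x mod 4]]`.
#'
#' @param cube H x W x n_bands numeric array with H, W divisible by 4.
#' @param layout A [moxel_layout()].
#' @return H x W numeric matrix of class `raw_mosaic` with the layout
#'   attached as attribute `layout`.
#' @export
mosaic <- function(cube, layout = default_layout()) {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  d <- dim(cube)
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0) {
    stop("mosaic: cube height and width must be divisible by 4")
  }
  if (d[3] != layout$n_bands) {
    stop("mosaic: cube band count must match the layout")
  }
  bm <- band_map(d[1], d[2], layout)
  idx <- cbind(as.vector(row(bm)), as.vector(col(bm)), as.vector(bm) + 1L)
  raw <- matrix(cube[idx], d[1], d[2])
  structure(raw, layout = layout, class = c("raw_mosaic", "matrix", "array"))
}

# 1-D fill: y has values at positions pos (sorted), NA elsewhere; linear
# interpolation between neighbours, nearest value beyond the outer samples
interp_line <- function(vals, pos, n) {
  out <- rep(NA_real_, n)
  out[pos] <- vals
  if (length(pos) == 1) return(rep(vals, n))
  stats::approx(pos, vals, xout = seq_len(n), method = "linear",
                rule = 2)$y
}

#' Bilinear demosaicking
#'
#' Reconstructs the full-resolution cube from a raw mosaic, band by band.
#' Two separable two-pass estimates are averaged: (rows-with-samples
#' interpolated along lines, then completed along columns) and
#' (columns-with-samples interpolated along columns, then completed along
#' lines). Sampled pixels keep their raw value exactly; beyond the
#' outermost samples of a line/column the nearest sample value is used.
#'
#' @param raw A [mosaic()] result, or a matrix plus an explicit `layout`.
#' @param layout A [moxel_layout()]; defaults to the one attached to `raw`.
#' @return H x W x n_bands numeric array.
#' @export
demosaic_bilinear <- function(raw, layout = attr(raw, "layout")) {
  if (is.null(layout)) stop("demosaic_bilinear: no layout attached or given")
  raw <- unclass(raw)
  h <- nrow(raw); w <- ncol(raw)
  bm <- band_map(h, w, layout)
  cube <- array(NA_real_, c(h, w, layout$n_bands))
  for (b in seq_len(layout$n_bands) - 1L) {
    mask <- bm == b
    if (!any(mask)) stop("demosaic_bilinear: band absent from layout")
    # pass A: lines first, then columns
    pa <- matrix(NA_real_, h, w)
    for (y in seq_len(h)) {
      pos <- which(mask[y, ])
      if (length(pos)) pa[y, ] <- interp_line(raw[y, pos], pos, w)
    }
    for (x in seq_len(w)) {
      pos <- which(!is.na(pa[, x]))
      pa[, x] <- interp_line(pa[pos, x], pos, h)
    }
    # pass B: columns first, then lines
    pb <- matrix(NA_real_, h, w)
    for (x in seq_len(w)) {
      pos <- which(mask[, x])
      if (length(pos)) pb[, x] <- interp_line(raw[pos, x], pos, h)
    }
    for (y in seq_len(h)) {
      pos <- which(!is.na(pb[y, ]))
      pb[y, ] <- interp_line(pb[y, pos], pos, w)
    }
    plane <- (pa + pb) / 2
    plane[mask] <- raw[mask]             # sampled pixels are exact
    cube[, , b + 1L] <- plane
  }
  cube
}

#' Lambertian-white calibration
#'
#' Normalizes a demosaicked cube by the cube of a perfectly diffuse white
#' reference acquired under the same illumination, converting linear sensor
#' units into reflectance factors. `epsilon` guards against division by
#' (near-)zero white pixels.
#'
#' @param cube,white H x W x n_bands numeric arrays of identical shape.
#' @param epsilon Positive floor applied to `white` (default 1e-6).
#' @return Array of reflectance factors, `cube / pmax(white, epsilon)`.
#' @export
white_calibrate <- function(cube, white, epsilon = 1e-6) {
  if (!identical(dim(cube), dim(white))) {
    stop("white_calibrate: cube and white must share one shape")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("white_calibrate: epsilon must be > 0")
  }
  cube / pmax(white, epsilon)
}

#' Extract the sparse samples of one band from a raw mosaic
#'
#' @param raw A [mosaic()] result (or matrix with `layout`).
#' @param band 0-based band index present in the layout.
#' @param layout A [moxel_layout()]; defaults to the attached one.
#' @return data.frame with columns `row`, `col` (1-based) and `value`;
#'   `n_l * n_c * multiplicity[band]` rows.
#' @export
extract_band_samples <- function(raw, band, layout = attr(raw, "layout")) {
  if (is.null(layout)) stop("extract_band_samples: no layout attached or given")
  if (!(band %in% (seq_len(layout$n_bands) - 1L))) {
    stop("extract_band_samples: unknown band")
  }
  raw <- unclass(raw)
  bm <- band_map(nrow(raw), ncol(raw), layout)
  idx <- which(bm == band, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2], value = raw[idx])
}

#' Read / write raw mosaics as ASCII PGM (P2)
#'
#' Plain-text portable graymap with 16-bit range, the on-disk format for
#' raw mosaics (text-only substitute for 16-bit TIFF/PNG).
#'
#' @param raw Numeric matrix in `[0, maxval]`.
#' @param path File path.
#' @param maxval Maximum gray value (default 65535).
#' @return `read_pgm` returns a numeric matrix; `write_pgm` returns `path`
#'   invisibly.
#' @export
write_pgm <- function(raw, path, maxval = 65535) {
  raw <- round(unclass(raw))
  if (any(raw < 0) || any(raw > maxval)) stop("write_pgm: values out of range")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(raw), nrow(raw)),
               sprintf("%d", maxval)), con)
  utils::write.table(raw, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("read_pgm: only ASCII (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("read_pgm: truncated pixel data")
  matrix(vals, h, w, byrow = TRUE)
}

#' Write / read a spectral cube as a stack of PGM pages
#'
#' One ASCII PGM file per band, `<prefix>_b01.pgm` ... in band order, plus
#' values scaled by `scale` and rounded.
#'
#' @param cube H x W x n_bands array.
#' @param prefix Path prefix.
#' @param scale Multiplier applied before rounding to integers (default
#'   65535, mapping [0, 1] data onto the 16-bit range).
#' @return `write_cube_pgm` returns the file paths invisibly; `read_cube_pgm`
#'   returns the array divided by `scale`.
#' @export
write_cube_pgm <- function(cube, prefix, scale = 65535) {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  paths <- character(dim(cube)[3])
  for (b in seq_len(dim(cube)[3])) {
    paths[b] <- sprintf("%s_b%02d.pgm", prefix, b)
    write_pgm(pmin(pmax(cube[, , b] * scale, 0), 65535), paths[b])
  }
  invisible(paths)
}

#' @rdname write_cube_pgm
#' @export
read_cube_pgm <- function(prefix, scale = 65535) {
  paths <- Sys.glob(sprintf("%s_b*.pgm", prefix))
  if (!length(paths)) stop("read_cube_pgm: no pages found")
  planes <- lapply(sort(paths), read_pgm)
  out <- array(0, c(dim(planes[[1]]), length(planes)))
  for (b in seq_along(planes)) out[, , b] <- planes[[b]] / scale
  out
}
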