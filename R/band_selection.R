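# Genetic-algorithm search for optimal MSFA band centers.
#
# Chromosome: real-valued vector of n_bands Gaussian filter centers, kept
# sorted and at least min_spacing apart after every operator. Fitness is
# the mean per-sample RMS of the Wiener reconstruction of the training
# reflectance set through the candidate bank (FWHM fixed, peak 1, SNR per
# settings). Design-study GA settings: population 100, crossover fraction
# 0.6, migration fraction 0.2, fitness limit 0.02 RMS.

#' GA settings for band selection
#'
#' Defaults follow the design study where stated (population 100, crossover
#' fraction 0.6, migration fraction 0.2, fitness limit 0.02, FWHM 30 nm,
#' SNR 100, 8 bands); operator details the study does not state (tournament
#' selection, elitism, mutation scale, island topology, spacing repair,
#' generation cap) use the documented defaults below.
#'
#' @param n_bands Number of filter centers to optimize (default 8).
#' @param bounds Length-2 numeric, search range in nm (default VIS preset
#'   380-680).
#' @param population_size Total population across islands (default 100).
#' @param crossover_fraction Fraction of offspring produced by blend
#'   crossover (default 0.6).
#' @param migration_fraction Fraction of each island migrated along the
#'   ring every `migration_interval` generations (default 0.2).
#' @param fitness_limit Stop when best mean RMS falls to or below this
#'   (default 0.02).
#' @param fwhm Filter FWHM during the search, nm (default 30).
#' @param snr Forward-model signal-to-noise ratio (default 100; `Inf` for
#'   noiseless).
#' @param max_generations Generation cap (default 200).
#' @param n_islands Number of subpopulations on a ring (default 2).
#' @param migration_interval Generations between migrations (default 10).
#' @param min_spacing Minimum distance between selected centers, nm
#'   (default 10), enforced by repair.
#' @param mutation_sd Per-gene Gaussian mutation standard deviation, nm
#'   (default 5).
#' @param elite Elites preserved per island per generation (default 2).
#' @param tournament Tournament size for selection (default 3).
#' @param seed Integer seed; same seed, same settings give identical runs.
#' @return An object of class `ga_settings`.
#' @export
ga_settings <- function(n_bands = 8, bounds = c(380, 680),
                        population_size = 100, crossover_fraction = 0.6,
                        migration_fraction = 0.2, fitness_limit = 0.02,
                        fwhm = 30, snr = 100, max_generations = 200,
                        n_islands = 2, migration_interval = 10,
                        min_spacing = 10, mutation_sd = 5,
                        elite = 2, tournament = 3, seed = 1) {
  if (population_size < 4) stop("ga_settings: population_size must be >= 4")
  if (crossover_fraction <= 0 || crossover_fraction >= 1) {
    stop("ga_settings: crossover_fraction must lie in (0, 1)")
  }
  if (migration_fraction < 0 || migration_fraction >= 1) {
    stop("ga_settings: migration_fraction must lie in [0, 1)")
  }
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("ga_settings: bounds must be (min, max) with min < max")
  }
  if ((bounds[2] - bounds[1]) < (n_bands - 1) * min_spacing) {
    stop("ga_settings: bounds too narrow for n_bands at min_spacing")
  }
  if (fwhm <= 0) stop("ga_settings: fwhm must be > 0")
  structure(list(n_bands = n_bands, bounds = bounds,
                 population_size = population_size,
                 crossover_fraction = crossover_fraction,
                 migration_fraction = migration_fraction,
                 fitness_limit = fitness_limit, fwhm = fwhm, snr = snr,
                 max_generations = max_generations, n_islands = n_islands,
                 migration_interval = migration_interval,
                 min_spacing = min_spacing, mutation_sd = mutation_sd,
                 elite = elite, tournament = tournament, seed = seed),
            class = "ga_settings")
}

#' Search-range presets for the dual-camera design
#'
#' `"vis"` covers 380-680 nm, `"nir"` 650-950 nm.
#'
#' @param which `"vis"` or `"nir"`.
#' @return Length-2 numeric bounds (nm).
#' @export
band_range_preset <- function(which = c("vis", "nir")) {
  which <- match.arg(which)
  if (which == "vis") c(380, 680) else c(650, 950)
}

# snap genes to the nearest unused candidate center (discrete search mode)
snap_to_candidates <- function(x, cand) {
  free <- rep(TRUE, length(cand))
  out <- numeric(length(x))
  for (i in order(x)) {
    j <- which(free)[which.min(abs(cand[free] - x[i]))]
    out[i] <- cand[j]
    free[j] <- FALSE
  }
  sort(out)
}

# sort + enforce minimum spacing inside bounds
repair_centers <- function(x, bounds, spacing) {
  x <- sort(pmin(pmax(x, bounds[1]), bounds[2]))
  n <- length(x)
  if (n > 1) {
    for (i in 2:n) x[i] <- max(x[i], x[i - 1] + spacing)
    if (x[n] > bounds[2]) {
      x[n] <- bounds[2]
      for (i in (n - 1):1) x[i] <- min(x[i], x[i + 1] - spacing)
    }
  }
  x
}

# Precomputes everything reusable across fitness evaluations and returns a
# deterministic function(centers) -> mean per-sample reconstruction RMS.
fitness_closure <- function(ds, settings, qe, illum) {
  grid <- ds$grid
  qe <- resample(qe, grid)
  spd <- resample(illum$spd, grid)
  base <- qe$values * spd$values * grid$step
  R <- ds$samples
  K <- nrow(R)
  Cr <- crossprod(R) / K
  Rt <- t(R)
  wl <- wavelengths(grid)
  sigma <- sigma_from_fwhm(settings$fwhm)
  noise_seed <- if (is.null(settings$seed)) 0L
                else as.integer(settings$seed %% 1000003L) + 7L
  function(centers) {
    centers <- sort(centers)
    A <- t(vapply(centers,
                  function(mu) exp(-((wl - mu)^2) / (2 * sigma^2)) * base,
                  numeric(grid$n)))
    O <- A %*% Rt
    v <- 0
    if (is.finite(settings$snr)) {
      sd <- mean(abs(O)) / settings$snr
      v <- sd^2
      # fixed substream: fitness must be a pure function of the centers
      rng <- get_rng_state()
      set.seed(noise_seed)
      O <- O + matrix(stats::rnorm(length(O), sd = sd), nrow(O), ncol(O))
      restore_rng_state(rng)
    }
    ACr <- A %*% Cr
    M <- ACr %*% t(A) + diag(v, nrow(A))
    W <- tryCatch(t(solve((M + t(M)) / 2, ACr)), error = function(e) NULL)
    if (is.null(W)) return(Inf)
    E <- t(W %*% O) - R
    mean(sqrt(rowMeans(E^2)))
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Band-selection fitness
#'
#' Builds a Gaussian bank at the candidate centers (FWHM from `settings`,
#' peak 1), forms the system matrix under `qe` and `illum`, simulates
#' responses at the settings' SNR (fixed noise substream, so the value is a
#' deterministic function of the centers), fits the Wiener estimator at the
#' matching noise variance, reconstructs the dataset and returns the mean
#' per-sample RMS. Invariant under permutation of `centers`.
#'
#' @param centers Candidate center wavelengths (nm), inside
#'   `settings$bounds`.
#' @param ds Training [reflectance_set()].
#' @param settings A [ga_settings()].
#' @param qe Sensor QE [spectrum_curve()].
#' @param illum An [illuminant()].
#' @return Mean per-sample reconstruction RMS (unitless).
#' @export
band_fitness <- function(centers, ds, settings, qe, illum) {
  if (any(centers < settings$bounds[1] - 1e-9) ||
      any(centers > settings$bounds[2] + 1e-9)) {
    stop("band_fitness: centers outside settings bounds")
  }
  fitness_closure(ds, settings, qe, illum)(centers)
}

#' Run the genetic algorithm for band selection
#'
#' Real-coded island GA: `n_islands` subpopulations on a ring exchange the
#' best `migration_fraction` of individuals every `migration_interval`
#' generations; selection is tournament-`tournament` with `elite` elites;
#' `crossover_fraction` of offspring come from blend crossover, the rest
#' from per-gene Gaussian mutation (sd `mutation_sd` nm); every chromosome
#' is repaired to sorted centers at least `min_spacing` apart inside the
#' bounds. Stops at `fitness_limit` or `max_generations`; the best-ever
#' individual is returned. Identical seed and settings give identical runs.
#'
#' @param ds Training [reflectance_set()], non-empty.
#' @param settings A [ga_settings()].
#' @param qe Sensor QE [spectrum_curve()]; default [gen_sensor_qe()] on the
#'   dataset grid.
#' @param illum An [illuminant()]; default standard illuminant A (the
#'   dataset-measurement illuminant).
#' @param evaluate_result Also attach a full [evaluate()] report for the
#'   winning bank (default TRUE).
#' @param candidates Optional vector of admissible center wavelengths;
#'   when given, the search is restricted to distinct candidates (every
#'   chromosome is snapped to the nearest unused candidate), which is the
#'   mode validated against [exhaustive_search()].
#' @return An object of class `band_selection_result`: `centers` (sorted),
#'   `best_fitness`, `fitness_history` (generation, best, mean),
#'   `terminated_by` (`"fitness_limit"` or `"max_generations"`), `report`.
#' @export
run_ga <- function(ds, settings = ga_settings(),
                   qe = gen_sensor_qe(ds$grid),
                   illum = standard_illuminant("A", ds$grid),
                   evaluate_result = TRUE, candidates = NULL) {
  stopifnot(inherits(ds, "reflectance_set"), inherits(settings, "ga_settings"))
  if (nrow(ds$samples) < 1) stop("run_ga: empty dataset")
  if (!is.null(candidates) && length(candidates) < settings$n_bands) {
    stop("run_ga: fewer candidates than bands")
  }
  fit <- fitness_closure(ds, settings, qe, illum)
  s <- settings
  repair <- if (is.null(candidates)) {
    function(x) repair_centers(x, s$bounds, s$min_spacing)
  } else {
    function(x) snap_to_candidates(x, candidates)
  }
  set.seed(as.integer(s$seed))
  n_isl <- max(1L, as.integer(s$n_islands))
  pop_n <- max(2L, floor(s$population_size / n_isl))
  lo <- s$bounds[1]; hi <- s$bounds[2]

  new_pop <- function() {
    m <- replicate(pop_n, repair(stats::runif(s$n_bands, lo, hi)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)   # n_bands == 1
    t(m)
  }
  islands <- replicate(n_isl, new_pop(), simplify = FALSE)
  scores <- lapply(islands, function(P) apply(P, 1, fit))

  best_x <- NULL; best_f <- Inf
  hist_best <- numeric(0); hist_mean <- numeric(0)
  terminated_by <- "max_generations"

  tournament_pick <- function(f) {
    idx <- sample.int(length(f), s$tournament, replace = TRUE)
    idx[which.min(f[idx])]
  }

  for (gen in seq_len(s$max_generations)) {
    for (j in seq_len(n_isl)) {
      P <- islands[[j]]; f <- scores[[j]]
      ord <- order(f)
      n_elite <- min(s$elite, pop_n)
      children <- matrix(0, pop_n, s$n_bands)
      children[seq_len(n_elite), ] <- P[ord[seq_len(n_elite)], , drop = FALSE]
      for (i in seq_len(pop_n - n_elite) + n_elite) {
        if (stats::runif(1) < s$crossover_fraction) {
          p1 <- P[tournament_pick(f), ]
          p2 <- P[tournament_pick(f), ]
          w <- stats::runif(s$n_bands)          # blend crossover
          child <- w * p1 + (1 - w) * p2
        } else {
          child <- P[tournament_pick(f), ]
          hit <- stats::runif(s$n_bands) < 1 / s$n_bands
          if (!any(hit)) hit[sample.int(s$n_bands, 1)] <- TRUE
          child[hit] <- child[hit] + stats::rnorm(sum(hit), sd = s$mutation_sd)
        }
        children[i, ] <- repair(child)
      }
      islands[[j]] <- children
      scores[[j]] <- apply(children, 1, fit)
    }

    if (n_isl > 1 && s$migration_fraction > 0 &&
        gen %% s$migration_interval == 0) {
      n_mig <- max(1L, floor(s$migration_fraction * pop_n))
      sel <- lapply(seq_len(n_isl), function(j) {
        ord <- order(scores[[j]])
        list(x = islands[[j]][ord[seq_len(n_mig)], , drop = FALSE],
             f = scores[[j]][ord[seq_len(n_mig)]])
      })
      for (j in seq_len(n_isl)) {
        src <- sel[[if (j == 1) n_isl else j - 1]]   # ring topology
        ord <- order(scores[[j]], decreasing = TRUE)
        repl <- ord[seq_len(n_mig)]
        islands[[j]][repl, ] <- src$x
        scores[[j]][repl] <- src$f
      }
    }

    all_f <- unlist(scores)
    gb <- min(all_f)
    if (gb < best_f) {
      best_f <- gb
      jb <- which.min(vapply(scores, min, numeric(1)))
      best_x <- islands[[jb]][which.min(scores[[jb]]), ]
    }
    hist_best <- c(hist_best, best_f)
    hist_mean <- c(hist_mean, mean(all_f[is.finite(all_f)]))
    if (best_f <= s$fitness_limit) {
      terminated_by <- "fitness_limit"
      break
    }
  }

  centers <- repair(best_x)
  report <- NULL
  if (evaluate_result) {
    grid <- ds$grid
    bank <- gaussian_bank(centers, fwhm = s$fwhm, peak = 1, grid = grid)
    A <- system_matrix(resample(qe, grid), bank,
                       illuminant(illum$name, resample(illum$spd, grid)))
    O <- camera_response(A, ds, snr = s$snr, seed = s$seed)
    est <- fit_wiener(A, ds, noise_variance = O$noise_sd^2)
    report <- evaluate(ds, reconstruct(est, O),
                       illum = standard_illuminant("A", grid))
  }
  structure(list(centers = centers, best_fitness = best_f,
                 fitness_history = data.frame(generation = seq_along(hist_best),
                                              best = hist_best,
                                              mean = hist_mean),
                 terminated_by = terminated_by, report = report,
                 settings = s),
            class = "band_selection_result")
}

#' @export
print.band_selection_result <- function(x, ...) {
  cat(sprintf("<band_selection_result> %d centers, best mean RMS %.5f (%s)\n",
              length(x$centers), x$best_fitness, x$terminated_by))
  cat("centers (nm):", paste(round(x$centers, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive-search baseline for band selection
#'
#' Evaluates [band_fitness()] on every `n_bands`-combination of the
#' candidate centers and returns the global optimum. Serves as the oracle
#' the GA is validated against on small instances.
#'
#' @param ds Training [reflectance_set()].
#' @param candidate_centers Candidate center wavelengths (nm).
#' @param n_bands Bands per combination.
#' @param settings A [ga_settings()] (bounds must cover the candidates).
#' @param qe,illum Forward-model curves as in [band_fitness()].
#' @param cap Maximum number of combinations to enumerate (default 20000).
#' @return A `band_selection_result` with `terminated_by = "exhaustive"`.
#' @export
exhaustive_search <- function(ds, candidate_centers, n_bands,
                              settings = ga_settings(n_bands = n_bands),
                              qe = gen_sensor_qe(ds$grid),
                              illum = standard_illuminant("A", ds$grid),
                              cap = 20000) {
  n_comb <- choose(length(candidate_centers), n_bands)
  if (n_comb > cap) {
    stop(sprintf("exhaustive_search: %d combinations exceed cap %d",
                 n_comb, cap))
  }
  fit <- fitness_closure(ds, settings, qe, illum)
  cand <- sort(candidate_centers)
  combs <- matrix(cand[utils::combn(seq_along(cand), n_bands)], nrow = n_bands)
  f <- apply(combs, 2, fit)
  i <- which.min(f)
  structure(list(centers = combs[, i], best_fitness = f[i],
                 fitness_history = data.frame(generation = 1,
                                              best = f[i], mean = mean(f)),
                 terminated_by = "exhaustive", report = NULL,
                 settings = settings),
            class = "band_selection_result")
}
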