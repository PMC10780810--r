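# Run configuration, pipeline driver and command-line front end.
#
# The pipeline composes the modules end to end: generate (or load) data,
# select bands, build the bank, simulate a scene, mosaic, demosaic,
# white-calibrate, characterize, and report. Every artifact is written
# with a provenance sidecar (config hash, seed, package version). The CLI
# subcommands are thin wrappers over the module functions.

#' Default sensor profile
#'
#' Geometry and depth constants of the monochrome CMOS sensor the dual
#' cameras are built on: 1600 x 1200 pixels of 4.5 um pitch (7.2 x 5.4 mm
#' active area), 10-bit output. The bit depth is used only to scale
#' synthetic raw images to integer range.
#'
#' @return Named list `width_px`, `height_px`, `pixel_pitch_um`,
#'   `image_width_mm`, `image_height_mm`, `bit_depth`, `max_dn`.
#' @export
sensor_profile <- function() {
  list(width_px = 1600L, height_px = 1200L, pixel_pitch_um = 4.5,
       image_width_mm = 1600 * 4.5 / 1000, image_height_mm = 1200 * 4.5 / 1000,
       bit_depth = 10L, max_dn = 2L^10L - 1L)
}

#' Read and validate a run configuration
#'
#' Plain-text JSON with optional blocks `stages` (character vector),
#' `seed`, `out_dir`, `ga` (fields of [ga_settings()]), `sweep`
#' (`start`, `stop`, `step`), `scene` (`height`, `width`, `kind`), `paths`
#' (`spectra`, `qe`, `layout`: CSV/layout files to load instead of
#' generating). Referenced files must exist; block fields are validated by
#' their module constructors before any stage runs.
#'
#' @param path JSON file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: config file not found")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$out_dir <- if (is.null(cfg$out_dir)) "msfa_run" else cfg$out_dir
  if (is.null(cfg$stages)) {
    cfg$stages <- c("gen-data", "select-bands", "simulate-scene",
                    "demosaic", "characterize", "balance", "report")
  }
  known <- c("gen-data", "select-bands", "simulate-scene", "demosaic",
             "characterize", "balance", "report")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("read_run_config: unknown stages: ",
                        paste(bad, collapse = ", "))
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) stop("read_run_config: missing input file: ", p)
  }
  ga_args <- cfg$ga
  if (!is.null(ga_args)) {
    cfg$ga_settings <- do.call(ga_settings, ga_args)   # validates the block
  }
  cfg$config_path <- path
  class(cfg) <- "run_config"
  cfg
}

# fan a global seed out to per-stage seeds by fixed offsets
stage_seed <- function(seed, stage) {
  offsets <- c(`gen-data` = 11L, `select-bands` = 23L, `simulate-scene` = 37L,
               demosaic = 41L, characterize = 53L, balance = 61L,
               report = 71L)
  (as.integer(seed) + offsets[[stage]]) %% 2147483647L
}

write_sidecar <- function(path, cfg, stage) {
  meta <- list(stage = stage,
               config_hash = unname(tools::md5sum(cfg$config_path)),
               seed = cfg$seed, stage_seed = stage_seed(cfg$seed, stage),
               package = "msfadesign",
               version = as.character(utils::packageVersion("msfadesign")))
  jsonlite::write_json(meta, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Run the simulation pipeline
#'
#' Executes the stages requested in the configuration in canonical order,
#' writing each artifact and its provenance sidecar into the run
#' directory. Any stage error is logged and propagated (non-zero exit when
#' driven from the CLI). Identical config and seed yield identical
#' artifacts.
#'
#' @param config A [read_run_config()] result or a path to a config file.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- wl_grid()
  log_msg <- function(...) message(sprintf(...))

  ds <- NULL; bank <- NULL; result <- NULL; cube <- NULL; demos <- NULL
  qe <- if (!is.null(cfg$paths$qe)) {
    s <- read_spectra_csv(cfg$paths$qe, kind = "qe")
    spectrum_curve(s$grid, s$samples[1, ], kind = "qe")
  } else gen_sensor_qe(grid)
  layout <- if (!is.null(cfg$paths$layout)) read_layout(cfg$paths$layout)
            else default_layout()

  for (stage in intersect(c("gen-data", "select-bands", "simulate-scene",
                            "demosaic", "characterize", "balance", "report"),
                          cfg$stages)) {
    log_msg("[msfadesign] stage %s", stage)
    sseed <- stage_seed(cfg$seed, stage)
    if (stage == "gen-data") {
      ds <- if (!is.null(cfg$paths$spectra)) read_spectra_csv(cfg$paths$spectra)
            else gen_reflectance_set(veg_params(seed = sseed), grid)
      out <- file.path(cfg$out_dir, "reflectance.csv")
      write_spectra_csv(ds, out); write_sidecar(out, cfg, stage)
    } else if (stage == "select-bands") {
      if (is.null(ds)) ds <- gen_reflectance_set(veg_params(seed = stage_seed(cfg$seed, "gen-data")), grid)
      st <- if (!is.null(cfg$ga_settings)) cfg$ga_settings
            else ga_settings(seed = sseed)
      result <- run_ga(ds, st, qe = qe)
      bank <- gaussian_bank(result$centers, fwhm = st$fwhm, grid = grid)
      out <- file.path(cfg$out_dir, "selected_bands.csv")
      utils::write.csv(data.frame(band = seq_along(result$centers),
                                  center_nm = result$centers), out,
                       row.names = FALSE)
      utils::write.csv(result$fitness_history,
                       file.path(cfg$out_dir, "fitness_history.csv"),
                       row.names = FALSE)
      write_sidecar(out, cfg, stage)
    } else if (stage == "simulate-scene") {
      sc <- cfg$scene
      h <- if (is.null(sc$height)) 64L else as.integer(sc$height)
      w <- if (is.null(sc$width)) 64L else as.integer(sc$width)
      kind <- if (is.null(sc$kind)) "cosine" else sc$kind
      cube <- gen_scene(h, w, n_bands = layout$n_bands, kind = kind,
                        seed = sseed)
      raw <- mosaic(cube, layout)
      out <- file.path(cfg$out_dir, "raw_mosaic.pgm")
      write_pgm(round(raw * sensor_profile()$max_dn), out,
                maxval = sensor_profile()$max_dn)
      write_sidecar(out, cfg, stage)
    } else if (stage == "demosaic") {
      if (is.null(cube)) stop("run_pipeline: demosaic requires simulate-scene")
      demos <- demosaic_bilinear(mosaic(cube, layout), layout)
      white <- array(1, dim(demos))
      cal <- white_calibrate(demos, white)
      out <- file.path(cfg$out_dir, "demosaicked")
      write_cube_pgm(pmin(pmax(cal, 0), 1), out)
      write_sidecar(paste0(out, "_b01.pgm"), cfg, stage)
    } else if (stage == "characterize") {
      bk <- if (is.null(bank)) measured_bank("VIS", grid) else bank
      stack <- simulate_sweep(qe, bk, snr = Inf, seed = sseed)
      rep_ <- characterization_report(estimate_filter_response(stack))
      out <- file.path(cfg$out_dir, "characterization.csv")
      utils::write.csv(rep_, out, row.names = FALSE)
      write_sidecar(out, cfg, stage)
    } else if (stage == "balance") {
      bk <- if (is.null(bank)) measured_bank("VIS", grid) else bank
      responses <- lapply(bk$bands, function(b) {
        spectrum_curve(grid, b$values * qe$values, kind = "qe")
      })
      bal <- energy_balance(standard_illuminant("D65", grid), responses)
      out <- file.path(cfg$out_dir, "energy_balance.csv")
      write_balance_csv(bal, out); write_sidecar(out, cfg, stage)
    } else if (stage == "report") {
      if (is.null(result) || is.null(result$report)) {
        log_msg("[msfadesign] report: no band-selection report available, skipping")
      } else {
        out <- file.path(cfg$out_dir, "reconstruction_report.csv")
        write_report_csv(result$report, out); write_sidecar(out, cfg, stage)
      }
    }
  }
  invisible(cfg$out_dir)
}

#' Command-line entry point
#'
#' `msfa_main(c("run", "--config", "cfg.json"))` runs [run_pipeline()];
#' subcommands `gen-data`, `select-bands`, `simulate-scene`, `demosaic`,
#' `characterize`, `balance` and `report` run a single stage by building a
#' one-stage config. See `inst/cli/msfa.R` for the Rscript wrapper.
#'
#' @param args Character vector of arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
msfa_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: msfa <run|gen-data|select-bands|simulate-scene|demosaic|",
    "             characterize|balance|report> [--config cfg.json]",
    "             [--seed N] [--out DIR]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(config = NULL, seed = 1L, out = "msfa_run")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("unknown or incomplete option: ", args[i]); return(invisible(1L))
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    if (!is.null(opts$config)) {
      cfg <- read_run_config(opts$config)
    } else {
      tmp <- tempfile(fileext = ".json")
      jsonlite::write_json(list(seed = as.integer(opts$seed),
                                out_dir = opts$out),
                           tmp, auto_unbox = TRUE)
      cfg <- read_run_config(tmp)
    }
    if (cmd != "run") {
      if (!cmd %in% cfg$stages) stop("unknown subcommand: ", cmd)
      cfg$stages <- if (cmd %in% c("demosaic", "report"))
        c(switch(cmd, demosaic = "simulate-scene",
                 report = "select-bands"), cmd) else cmd
      if (cmd == "report" && is.null(cfg$ga)) {
        cfg$ga_settings <- ga_settings(max_generations = 20,
                                       seed = as.integer(opts$seed))
      }
    }
    run_pipeline(cfg)
    0L
  }, error = function(e) {
    message("msfa: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
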