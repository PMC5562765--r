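## End-to-end orchestration: phantom or file input -> segmentation ->
## elastography -> spectra -> angiography -> gating, with reproducible
## artifacts (velocity maps, spectra CSV, summary JSON, flux table, gated
## maps, resolved config, log).

#' Pipeline configuration
#'
#' @param input Path to an HDF5 volume ([read_volume()] dialect) or `NULL`
#'   when `phantom` is given.
#' @param phantom Name of a [phantom_presets()] entry to simulate instead of
#'   reading a file.
#' @param seed Integer seed for phantom generation.
#' @param roi Optional region of interest (see [frame_mean_velocity()]).
#' @param cs_depth Chorioscleral analysis depth in pixels (`NULL` = all below
#'   the RPE).
#' @param window,overlap STFT parameters.
#' @param hr_band Heart-rate search band in Hz.
#' @param clean_limit Frame-exclusion circular-variance limit.
#' @param scp_frac,angio_cs_depth,scales Angiography slab/vesselness
#'   parameters.
#' @param onh_diameter_frac ONH exclusion-disk diameter as a fraction of the
#'   A-scan count (default 150/512); `NULL` disables the exclusion.
#' @param n_bins,n_adjacent Cardiac gating parameters.
#' @param velocity_cutoff Threshold for gated motion regions, m/s.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, phantom = NULL, seed = 1L,
                            roi = NULL, cs_depth = NULL,
                            window = 256, overlap = 0.75,
                            hr_band = c(2, 10), clean_limit = 0.5,
                            scp_frac = 0.6, angio_cs_depth = 40,
                            scales = c(2, 4, 8),
                            onh_diameter_frac = 150 / 512,
                            n_bins = 20, n_adjacent = 3,
                            velocity_cutoff = 12e-6,
                            out_dir = "octpulse-out") {
  if (is.null(input) && is.null(phantom))
    stop_usage("pipeline needs an input file or a phantom preset name")
  structure(list(input = input, phantom = phantom, seed = as.integer(seed),
                 roi = roi, cs_depth = cs_depth, window = window,
                 overlap = overlap, hr_band = hr_band,
                 clean_limit = clean_limit, scp_frac = scp_frac,
                 angio_cs_depth = angio_cs_depth, scales = scales,
                 onh_diameter_frac = onh_diameter_frac, n_bins = n_bins,
                 n_adjacent = n_adjacent, velocity_cutoff = velocity_cutoff,
                 out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_input <- function(config) {
  if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop_usage("input volume not found: ", config$input)
    read_volume(config$input)
  } else {
    presets <- phantom_presets(seed = config$seed)
    if (!config$phantom %in% names(presets))
      stop_usage("unknown phantom preset '", config$phantom, "'; available: ",
                 paste(names(presets), collapse = ", "))
    generate_phantom(presets[[config$phantom]])$volume
  }
}

write_gated_tiff <- function(gated, path) {
  pages <- lapply(seq_len(gated$n_bins), function(b) {
    m <- gated$maps[, , b]
    rng <- range(m, na.rm = TRUE)
    if (!all(is.finite(rng)) || diff(rng) == 0) rng <- c(0, 1)
    norm <- (m - rng[1]) / diff(rng)
    norm[is.na(norm)] <- 0
    norm
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(n_bins = gated$n_bins, units = gated$units,
                            note = "per-bin affine normalization"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Run the multi-functional pipeline
#'
#' Executes phantom/file input, layer segmentation, surface-normal fitting,
#' velocity-field computation and cleaning, per-frame averaging, STFT
#' pulsatility analysis, displacement amplitude, per-plexus angiography flux,
#' and cardiac gating; writes all artifacts plus the resolved configuration
#' and a stage log into `config$out_dir`. Identical seed and configuration
#' yield identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param through Last stage to execute: `"segment"`, `"pulsation"`,
#'   `"spectra"`, `"angio"`, `"gate"` or `"all"` (default). Earlier stages a
#'   later one depends on always run; artifacts are written for every stage
#'   that ran.
#' @return Invisibly, a list with the result objects that were computed
#'   (`spectrum`, `series`, `flux`, `gated`, `field`, `layers`, file `paths`).
#' @export
run_pipeline <- function(config, through = c("all", "segment", "pulsation",
                                             "spectra", "angio", "gate")) {
  if (!inherits(config, "pipeline_config"))
    stop_usage("config must be a pipeline_config")
  through <- match.arg(through)
  want <- function(stage) {
    deps <- list(segment = "segment",
                 pulsation = c("segment", "pulsation"),
                 spectra = c("segment", "pulsation", "spectra"),
                 angio = c("segment", "angio"),
                 gate = c("segment", "pulsation", "spectra", "gate"),
                 all = c("segment", "pulsation", "spectra", "angio", "gate"))
    stage %in% deps[[through]]
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(sprintf("stage %-12s %6.2f s", name, proc.time()[["elapsed"]] - t0))
    out
  }

  paths <- list(
    surfaces = file.path(config$out_dir, "surfaces.csv"),
    velocity = file.path(config$out_dir, "velocity_enface.tiff"),
    spectra = file.path(config$out_dir, "spectra.csv"),
    summary = file.path(config$out_dir, "summary.json"),
    flux = file.path(config$out_dir, "flux.csv"),
    gated = file.path(config$out_dir, "gated_maps.tiff"),
    config = file.path(config$out_dir, "config.json"),
    log = logf
  )
  field <- series <- spectrum <- fluxes <- gated <- NULL
  disp <- NA_real_

  volume <- stage("input", pipeline_input(config))
  layers <- stage("segment", fit_surface_normals(segment_layers(volume)))
  idx <- which(layers$valid | !layers$valid, arr.ind = TRUE)
  write.csv(data.frame(x = idx[, 1], position = idx[, 2],
                       z_ilm = layers$z_I[idx], z_rpe = layers$z_R[idx],
                       alpha_rad = layers$alpha[idx],
                       valid = layers$valid[idx]),
            paths$surfaces, row.names = FALSE)

  if (want("pulsation")) {
    field <- stage("pulsation", {
      f <- compute_velocity_field(volume, layers, cs_depth = config$cs_depth)
      clean_series(f, limit = config$clean_limit)
    })
    say(sprintf("excluded frames: %d / %d", sum(field$frame_stats$excluded),
                nrow(field$frame_stats)))
    series <- frame_mean_velocity(field, roi = config$roi)
    vmap <- enface_map(field$v_rcs, units = "m/s",
                       valid = field$valid | field$interpolated)
    write_enface(vmap, paths$velocity, "tiff")
  }

  if (want("spectra")) {
    spectrum <- stage("spectra", {
      sp <- stft_spectra(series, window = config$window,
                         overlap = config$overlap)
      extract_fundamental(sp, hr_band = config$hr_band)
    })
    disp <- if (!isTRUE(spectrum$no_pulsation)) {
      tryCatch(displacement_amplitude(series, spectrum$f0),
               error = function(e) NA_real_)
    } else NA_real_
    sp_df <- data.frame(frequency_hz = spectrum$freq,
                        mean_amplitude = spectrum$mean_spectrum)
    band_df <- as.data.frame(spectrum$bands)
    names(band_df) <- sprintf("band_%02d", seq_len(ncol(band_df)))
    write.csv(cbind(sp_df, band_df), paths$spectra, row.names = FALSE)
    jsonlite::write_json(list(
      f0_hz = spectrum$f0,
      heart_rate_bpm = heart_rate_bpm(spectrum$f0),
      A_fund_ms = spectrum$A_fund,
      A_harm1_ms = spectrum$A_harm1,
      A_harm2_ms = spectrum$A_harm2,
      no_pulsation = isTRUE(spectrum$no_pulsation),
      displacement_pp_m = disp,
      excluded_frames = sum(field$frame_stats$excluded),
      n_frames = nrow(field$frame_stats)
    ), paths$summary, auto_unbox = TRUE, digits = NA)
  }

  if (want("angio")) {
    fluxes <- stage("angio", {
      onh <- if (!is.null(config$onh_diameter_frac))
        list(center = NULL,
             diameter_px = round(config$onh_diameter_frac *
                                   volume$meta$n_ascans))
      else NULL
      angio_flux(volume, layers, scp_frac = config$scp_frac,
                 cs_depth = config$angio_cs_depth, scales = config$scales,
                 onh = onh)
    })
    write.csv(as.data.frame(fluxes[, c("slab", "flux", "n_pixels")]),
              paths$flux, row.names = FALSE)
  }

  if (want("gate")) {
    gated <- if (!isTRUE(spectrum$no_pulsation)) {
      stage("gate", {
        g <- assign_cardiac_phase(series, spectrum$f0)
        gate_and_average(field, g, n_bins = config$n_bins,
                         n_adjacent = config$n_adjacent)
      })
    } else {
      say("gating skipped: no pulsation detected")
      NULL
    }
    if (!is.null(gated)) write_gated_tiff(gated, paths$gated)
  }

  cfg_out <- unclass(config)
  cfg_out$roi <- cfg_out$roi %||% "full"
  cfg_out$cs_depth <- cfg_out$cs_depth %||% "below-RPE"
  jsonlite::write_json(cfg_out, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  writeLines(log_lines, logf)

  invisible(list(spectrum = spectrum, series = series, flux = fluxes,
                 gated = gated, field = field, layers = layers,
                 displacement = disp, paths = paths))
}

#' Command-line interface
#'
#' Thin argument-vector interface used by the `inst/cli/octpulse` Rscript.
#' Subcommands: `simulate` (write a phantom volume to HDF5), `segment`,
#' `pulsation`, `spectra`, `angio`, `gate` (run the pipeline up to the named
#' stage) and `run-all`. Options use `--key value` (or `--key=value`) pairs
#' mirroring [pipeline_config()] fields, plus `--config file.yaml`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, 0 on success (invisibly).
#' @export
octpulse_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: octpulse <simulate|segment|pulsation|spectra|angio|gate|run-all>",
    "[--phantom name] [--input file.h5] [--seed n] [--out dir]",
    "[--config file.yaml]", sep = "\n  ")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    a <- rest[i]
    if (grepl("^--[a-z-]+=", a)) {
      key <- sub("^--([a-z-]+)=.*$", "\\1", a)
      opts[[gsub("-", "_", key)]] <- sub("^--[a-z-]+=", "", a)
      i <- i + 1
    } else if (grepl("^--", a)) {
      key <- gsub("-", "_", sub("^--", "", a))
      opts[[key]] <- if (i < length(rest)) rest[i + 1] else ""
      i <- i + 2
    } else {
      message("unexpected argument: ", a, "\n", usage)
      return(invisible(1L))
    }
  }
  if (!is.null(opts$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_usage("YAML configs need the 'yaml' package")
    opts <- modifyList(yaml::yaml.load_file(opts$config), opts)
    opts$config <- NULL
  }
  out_dir <- opts$out %||% "octpulse-out"
  seed <- as.integer(opts$seed %||% 1L)

  run <- function(through) {
    cfg <- pipeline_config(
      input = opts$input, phantom = opts$phantom, seed = seed,
      window = as.numeric(opts$window %||% 256),
      overlap = as.numeric(opts$overlap %||% 0.75),
      out_dir = out_dir)
    run_pipeline(cfg, through = through)
  }
  status <- tryCatch({
    stages <- c(segment = "segment", pulsation = "pulsation",
                spectra = "spectra", angio = "angio", gate = "gate",
                "run-all" = "all")
    if (cmd == "simulate") {
      presets <- phantom_presets(seed = seed)
      name <- opts$phantom %||% "pulsing_65mmhg_like"
      if (!name %in% names(presets))
        stop_usage("unknown phantom preset '", name, "'")
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      ph <- generate_phantom(presets[[name]])
      p <- file.path(out_dir, paste0(name, ".h5"))
      write_volume(ph$volume, p)
      message("wrote ", p)
    } else if (cmd %in% names(stages)) {
      invisible(run(stages[[cmd]]))
    } else {
      message("unknown subcommand '", cmd, "'\n", usage)
      return(invisible(1L))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
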