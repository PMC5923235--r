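# Readers, writers and the pipeline entry point. Units are fixed
# package-wide (um, s, camera counts, densities um^-2); any conversion
# happens at this boundary. Frame indices are 0-based, as exported by the
# tracking software.

#' Track table container
#'
#' @param df Data frame with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   and optionally `intensity`, `channel`.
#' @param frame_interval Frame time (s).
#' @param validate_length Require every track to span >= 2 frames.
#' @return The data frame with class `track_table` and a `frame_interval`
#'   attribute; rows ordered by track and frame.
#' @export
track_table <- function(df, frame_interval = 0.030, validate_length = TRUE) {
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("track table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"intensity" %in% names(df)) df$intensity <- rep(NA_real_, nrow(df))
  if (!"channel" %in% names(df)) df$channel <- rep(NA_character_, nrow(df))
  df <- df[order(df$track_id, df$frame),
           c(need, "intensity", "channel"), drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 0) {
    dup <- unlist(lapply(split(df$frame, df$track_id),
                         function(f) any(diff(f) <= 0)))
    if (any(dup)) stop("frames must be strictly increasing within a track")
    if (validate_length) {
      lens <- table(df$track_id)
      if (any(lens < 2)) stop("tracks must span at least 2 frames")
    }
  }
  stopifnot(frame_interval > 0)
  structure(df, frame_interval = frame_interval,
            class = c("track_table", "data.frame"))
}

#' Read a track table from CSV
#'
#' Accepts the package's native header (`track_id, frame, x_um, y_um,
#' intensity, channel`) or TrackMate-style exports (`TRACK_ID, FRAME,
#' POSITION_X, POSITION_Y`, intensity aliases accepted). Tracks shorter
#' than `min_track_length` frames are dropped (the tracker cut-off that
#' rejects spurious detections); the number dropped is reported via the
#' `dropped_tracks` attribute and a message.
#'
#' @param path CSV path.
#' @param dialect `"auto"`, `"native"` or `"trackmate"`.
#' @param frame_interval Frame time (s).
#' @param min_track_length Minimum retained track length in frames.
#' @return A [track_table()].
#' @export
parse_track_table <- function(path, dialect = c("auto", "native",
                                                "trackmate"),
                              frame_interval = 0.030,
                              min_track_length = 3L) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  # TrackMate writes up to 3 extra header lines of labels/units; drop any
  # leading rows whose ID fields are not numeric
  nm <- names(df)
  native <- all(c("track_id", "frame", "x_um", "y_um") %in% nm)
  trackmate <- all(c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
                   %in% nm)
  if (dialect == "native" && !native ||
      dialect == "trackmate" && !trackmate ||
      dialect == "auto" && !native && !trackmate) {
    stop("unrecognised track table header; accepted dialects: native ",
         "(track_id, frame, x_um, y_um[, intensity, channel]) or ",
         "trackmate (TRACK_ID, FRAME, POSITION_X, POSITION_Y)")
  }
  if ((dialect == "auto" && !native) || dialect == "trackmate") {
    alias <- c(TRACK_ID = "track_id", FRAME = "frame",
               POSITION_X = "x_um", POSITION_Y = "y_um",
               MEAN_INTENSITY = "intensity", TOTAL_INTENSITY = "intensity",
               MEAN_INTENSITY_CH1 = "intensity")
    hit <- nm %in% names(alias)
    names(df)[hit] <- alias[nm[hit]]
    df <- df[!duplicated(names(df))]
    num <- suppressWarnings(as.numeric(df$frame))
    df <- df[!is.na(num), , drop = FALSE]
    for (cc in c("track_id", "frame", "x_um", "y_um")) {
      df[[cc]] <- as.numeric(df[[cc]])
    }
  }
  lens <- table(df$track_id)
  short <- names(lens)[lens < min_track_length]
  if (length(short) > 0) {
    df <- df[!(df$track_id %in% short), , drop = FALSE]
    message(length(short), " track(s) below the ", min_track_length,
            "-frame cut-off dropped")
  }
  tt <- track_table(df, frame_interval = frame_interval)
  attr(tt, "dropped_tracks") <- length(short)
  tt
}

#' Write a track table to CSV (native dialect)
#' @param tracks A [track_table()].
#' @param path Output path.
#' @export
write_track_table <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_table"))
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation trace to CSV
#' @param trace A `sim_trace`.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sim_trace"))
  df <- data.frame(time_s = trace$times, n_monomer = trace$n_monomer,
                   n_dimer = trace$n_dimer,
                   n_collisions = trace$n_collisions)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write two-column spectra and distance distributions
#'
#' Spectra CSVs have columns `wavelength_nm, intensity`; distance
#' distribution CSVs have `r_nm, density`.
#'
#' @param path CSV path.
#' @param excitation_label,sample_label Labels attached on read.
#' @return The corresponding container.
#' @export
read_spectrum_csv <- function(path, excitation_label = "donor",
                              sample_label = "mixed") {
  df <- read.csv(path)
  emission_spectrum(df$wavelength_nm, df$intensity, excitation_label,
                    sample_label)
}

#' @rdname read_spectrum_csv
#' @param spectrum An [emission_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(data.frame(wavelength_nm = spectrum$wavelength_nm,
                       intensity = spectrum$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectrum_csv
#' @export
read_distance_distribution_csv <- function(path) {
  df <- read.csv(path)
  distance_distribution(df$r_nm, df$density, normalise = FALSE)
}

#' @rdname read_spectrum_csv
#' @param distribution A [distance_distribution()].
#' @export
write_distance_distribution_csv <- function(distribution, path) {
  write.csv(data.frame(r_nm = distribution$r_nm,
                       density = distribution$density),
            path, row.names = FALSE)
  invisible(path)
}

#' Serialise a result list to JSON with full precision
#'
#' Floating point values keep 17 significant digits so a write-then-read
#' round trip reproduces them exactly.
#'
#' @param x A list (e.g. a `rate_set`).
#' @param path Output path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Pipeline configuration
#'
#' Validates and completes a configuration list (or a YAML file with the
#' same keys). Recognised blocks: `frame_interval`, `seed`, `kinetics`
#' (`k_on`, `k_off`), `synth` (`n_tracks`, `D`, `mean_length`,
#' `loc_noise`), `simulate` (passed to [sim_config()]), `smfret`, and
#' `interface`.
#'
#' @param config A named list or a path to a YAML file.
#' @return Validated configuration of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    frame_interval = 0.030,
    seed = 1L,
    kinetics = list(k_on = 0.081, k_off = 0.58),
    synth = list(n_tracks = 500L, D = 1.63, mean_length = 12,
                 loc_noise = 0),
    simulate = list(n_particles = 100L, density = 10, p_collision = 0.002,
                    k_off = 0.58, duration = 0.5),
    smfret = list(n_traces = 50L, n_frames = 100L),
    interface = list(m_models = 4L, n_sites = 8L, noise_sd = 0.05))
  merge2 <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(b[[nm]]) && is.list(a[[nm]])) {
        merge2(a[[nm]], b[[nm]])
      } else b[[nm]]
    }
    a
  }
  cfg <- merge2(defaults, config)
  stopifnot(cfg$frame_interval > 0, cfg$kinetics$k_on >= 0,
            cfg$kinetics$k_off > 0, cfg$synth$n_tracks >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run pipeline stages
#'
#' Thin orchestration over the package's analysis functions: each requested
#' stage reads its inputs (from earlier stages where applicable), runs the
#' corresponding module, and writes versioned outputs plus the seed and
#' parameters used into `out_dir`. With the same configuration and seed the
#' outputs are numerically identical across runs.
#'
#' Stages: `synth` (Brownian track table), `kinetics` (MSD fit and derived
#' rate constants; needs `synth`), `simulate` (a particle-simulator trace),
#' `smfret` (two-state traces, mixture fit, threshold, dwells), `interface`
#' (synthetic model matrix and subset ranking).
#'
#' @param config A [pipeline_config()] (or list/YAML path coerced to one).
#' @param stages Character vector of stage names, run in dependency order.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = character(0),
                         out_dir = tempfile("pipeline")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  valid <- c("synth", "kinetics", "simulate", "smfret", "interface")
  bad <- setdiff(stages, valid)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "))
  }
  if (length(stages) == 0) return(invisible(list(config = config)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- valid[valid %in% stages]  # dependency order
  res <- list(config = config)
  write_result_json(unclass(config), file.path(out_dir, "config.json"))
  for (st in stages) {
    res[[st]] <- switch(st,
      synth = {
        tt <- gen_brownian_tracks(
          n_tracks = config$synth$n_tracks, D = config$synth$D,
          frame_interval = config$frame_interval,
          mean_length = config$synth$mean_length,
          loc_noise = config$synth$loc_noise, seed = config$seed)
        write_track_table(tt, file.path(out_dir, "tracks.csv"))
        write_result_json(attr(tt, "truth"),
                          file.path(out_dir, "tracks_truth.json"))
        tt
      },
      kinetics = {
        tp <- file.path(out_dir, "tracks.csv")
        if (!file.exists(tp)) {
          stop("stage 'kinetics' needs the output of stage 'synth'; ",
               "run 'synth' first")
        }
        tt <- parse_track_table(tp, frame_interval = config$frame_interval)
        fit <- fit_diffusion(msd_curve(tt, max_lag = 8), n_fit_lags = 4)
        rates <- derive_rate_constants(k_on = config$kinetics$k_on,
                                       k_off = config$kinetics$k_off)
        out <- c(unclass(rates), list(D_fit = fit$D, D_ci = fit$ci))
        write_result_json(out, file.path(out_dir, "rates.json"))
        out
      },
      simulate = {
        sc <- do.call(sim_config, c(config$simulate,
                                    list(seed = config$seed)))
        tr <- suppressWarnings(run_simulation(sc))
        write_trace_csv(tr, file.path(out_dir, "trace.csv"))
        tr
      },
      smfret = {
        ts <- gen_fret_intensity_traces(config$smfret$n_traces,
                                        config$smfret$n_frames,
                                        seed = config$seed)
        acc <- unlist(lapply(ts$traces, `[[`, "acceptor"))
        mix <- fit_log_intensity_mixture(acc[acc > 0], k_range = 1:2,
                                         seed = config$seed)
        low <- mix$models[[paste0("k", mix$best_k)]]
        thr <- high_state_threshold(low$means[1], low$sds[1])
        dw <- do.call(rbind, lapply(ts$traces, function(tr) {
          segment_dwells(tr$acceptor, thr,
                         config$frame_interval)$dwells
        }))
        write.csv(dw, file.path(out_dir, "dwells.csv"), row.names = FALSE)
        list(mixture = mix, threshold = thr, dwells = dw)
      },
      interface = {
        ds <- gen_interface_dataset(config$interface$m_models,
                                    config$interface$n_sites,
                                    noise_sd = config$interface$noise_sd,
                                    seed = config$seed)
        rk <- enumerate_subsets(ds$experimental, ds$models)
        write_result_json(
          list(best_subset = rk$best$subset,
               coefficients = as.list(rk$best$coefficients),
               table = rk$table),
          file.path(out_dir, "interface_fits.json"))
        rk
      })
  }
  invisible(res)
}
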