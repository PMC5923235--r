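# Generators producing inputs with the statistical structure the analysis
# modules assume: Brownian track tables, two-channel dimerisation movies,
# two-state FRET intensity traces, model matrices and DEER mixtures.
# Every generator is deterministic per seed and attaches the generating
# parameters as a `truth` attribute; round-trip tests read the truth only
# to assert, never to estimate.

.truth <- function(...) {
  t <- list(...)
  t$generated_at <- NA  # no wall-clock: outputs must be seed-reproducible
  t
}

#' Generate independent 2D Brownian tracks
#'
#' Tracks sampled at the camera frame interval with per-axis displacement
#' sd `sqrt(2 D dt)` plus optional Gaussian localisation noise. Track
#' lengths are drawn from a shifted geometric distribution, mimicking
#' bleach-limited observation.
#'
#' @param n_tracks Number of tracks.
#' @param D Diffusion coefficient (um^2/s).
#' @param frame_interval Frame time (s).
#' @param mean_length Mean track length in frames.
#' @param min_length Minimum track length (the tracker's cut-off is 3).
#' @param loc_noise Localisation noise sd (um) added per coordinate.
#' @param seed Integer seed.
#' @return A [track_table()] with a `truth` attribute.
#' @export
gen_brownian_tracks <- function(n_tracks, D = 1.63, frame_interval = 0.030,
                                mean_length = 12, min_length = 3L,
                                loc_noise = 0, seed = 1L) {
  stopifnot(n_tracks >= 1, D >= 0, frame_interval > 0,
            mean_length >= min_length, loc_noise >= 0)
  set.seed(seed)
  lens <- min_length + rgeom(n_tracks, 1 / (mean_length - min_length + 1))
  raw <- brownian_tracks_cpp(n_tracks, as.integer(lens), D, frame_interval,
                             loc_noise, as.double(seed) + 7573)
  df <- data.frame(track_id = raw$track_id, frame = raw$frame,
                   x_um = raw$x_um, y_um = raw$y_um,
                   intensity = NA_real_, channel = "donor")
  tt <- track_table(df, frame_interval = frame_interval)
  attr(tt, "truth") <- .truth(D = D, frame_interval = frame_interval,
                              mean_length = mean_length,
                              min_length = min_length,
                              loc_noise = loc_noise, seed = seed,
                              n_tracks = n_tracks)
  tt
}

#' Generate a two-channel single-molecule dimerisation movie
#'
#' Runs the particle simulator with per-protomer fluorophore labels and
#' renders what the two camera channels would track: the donor channel sees
#' particles carrying an unbleached donor that is not FRET-quenched (donor
#' monomers, donor-donor and donor-dark dimers); the acceptor channel sees
#' FRET-visible donor-acceptor dimers only. Each fluorophore photobleaches
#' in a single step after an exponential lifetime. Appearance times of new
#' acceptor-channel tracks are the observable dimer-formation events.
#'
#' @param config A [sim_config()].
#' @param labelling Fractions `(f_donor, f_acceptor, f_unlabelled)`, summing
#'   to 1. Default is the experimental 100:405:45 ratio.
#' @param bleach_rates Bleach rates `(donor, acceptor)` in s^-1.
#' @param frame_interval Camera frame time (s).
#' @param intensity_log_mean,intensity_log_sd Lognormal spot intensity
#'   parameters (camera counts, log scale).
#' @param seed Integer seed (labels, bleaching, intensities; the simulator
#'   itself uses `config$seed`).
#' @return List of class `dimer_movie`: `donor` and `acceptor`
#'   [track_table()]s, `events` (formation times in s), `truth`.
#' @export
gen_dimerisation_movie <- function(config,
                                   labelling = c(100, 405, 45) / 550,
                                   bleach_rates = c(0.4, 0.4),
                                   frame_interval = 0.030,
                                   intensity_log_mean = log(400),
                                   intensity_log_sd = 0.35,
                                   seed = 1L) {
  stopifnot(inherits(config, "sim_config"), length(labelling) == 3)
  if (abs(sum(labelling) - 1) > 1e-9) stop("labelling fractions must sum to 1")
  trace <- suppressWarnings(
    run_simulation(config, record_frames = frame_interval))
  fr <- trace$frames
  if (is.null(fr)) stop("simulation recorded no frames")
  n_frames <- fr$n_frames
  n_rec <- config$n_particles
  set.seed(seed)
  label <- sample(c("D", "A", "U"), n_rec, replace = TRUE, prob = labelling)
  bleach_at <- rep(Inf, n_rec)  # unlabelled (or rate 0) never bleaches
  is_d <- label == "D"; is_a <- label == "A"
  if (bleach_rates[1] > 0) bleach_at[is_d] <- rexp(sum(is_d),
                                                   bleach_rates[1])
  if (bleach_rates[2] > 0) bleach_at[is_a] <- rexp(sum(is_a),
                                                   bleach_rates[2])
  base_int <- rlnorm(n_rec, intensity_log_mean, intensity_log_sd)

  don <- list(); acc <- list()
  acc_open <- list()   # key -> first frame of current episode
  events <- numeric(0)
  for (f in seq_len(n_frames)) {
    t <- fr$time[f]
    n <- fr$n[f]
    idx <- seq_len(n)
    sp <- fr$species[f, idx]
    i1 <- fr$id1[f, idx] + 1L  # 0-based ids from the simulator
    i2 <- ifelse(sp == 1L, fr$id2[f, idx] + 1L, NA_integer_)
    lab1 <- label[i1]
    alive1 <- bleach_at[i1] > t
    lab2 <- label[i2]                    # NA for monomers
    alive2 <- !is.na(i2) & bleach_at[ifelse(is.na(i2), 1L, i2)] > t
    has_live_D <- (lab1 == "D" & alive1) |
      (!is.na(lab2) & lab2 == "D" & alive2)
    has_live_A <- (lab1 == "A" & alive1) |
      (!is.na(lab2) & lab2 == "A" & alive2)
    fretting <- sp == 1L & has_live_D & has_live_A
    donor_vis <- has_live_D & !fretting
    if (any(donor_vis)) {
      j <- idx[donor_vis]
      did <- ifelse(lab1[j] == "D" & alive1[j], i1[j], i2[j])
      don[[length(don) + 1L]] <- data.frame(
        track_id = did, frame = f - 1L,
        x_um = fr$x[f, j], y_um = fr$y[f, j],
        intensity = base_int[did], channel = "donor")
    }
    open_now <- character(0)
    if (any(fretting)) {
      j <- idx[fretting]
      key <- paste(pmin(i1[j], i2[j]), pmax(i1[j], i2[j]), sep = "_")
      open_now <- key
      new_ep <- !(key %in% names(acc_open))
      if (any(new_ep)) {
        for (kk in key[new_ep]) acc_open[[kk]] <- t
        events <- c(events, rep(t, sum(new_ep)))
      }
      acc[[length(acc) + 1L]] <- data.frame(
        track_id = key, frame = f - 1L,
        x_um = fr$x[f, j], y_um = fr$y[f, j],
        intensity = (base_int[i1[j]] + base_int[i2[j]]) / 2,
        channel = "acceptor")
    }
    acc_open <- acc_open[names(acc_open) %in% open_now]
  }
  mk <- function(lst, channel) {
    if (length(lst) == 0) {
      df <- data.frame(track_id = integer(0), frame = integer(0),
                       x_um = numeric(0), y_um = numeric(0),
                       intensity = numeric(0), channel = character(0))
    } else {
      df <- do.call(rbind, lst)
      df$track_id <- as.integer(factor(df$track_id))
      df <- df[order(df$track_id, df$frame), ]
    }
    track_table(df, frame_interval = frame_interval, validate_length = FALSE)
  }
  truth <- .truth(
    config = unclass(config), labelling = labelling,
    bleach_rates = bleach_rates, frame_interval = frame_interval,
    seed = seed,
    total_associations = trace$total_associations,
    duration = config$duration, area = config$box_side^2,
    true_formation_rate = trace$total_associations /
      (config$box_side^2 * config$duration))
  structure(list(donor = mk(don, "donor"), acceptor = mk(acc, "acceptor"),
                 events = events, truth = truth, trace = trace),
            class = "dimer_movie")
}

#' Generate dimer-formation event times under photobleaching decay
#'
#' Draws appearance times of FRET-visible dimer-formation events in
#' repeated observation windows as an inhomogeneous Poisson process with
#' areal rate `rate0 * exp(-decay t)` (photobleaching depletes the visible
#' pool exponentially).
#'
#' @param rate0 Visible areal formation rate at illumination start
#'   (um^-2 s^-1).
#' @param decay Bleach decay constant (s^-1).
#' @param windows Per-video observation durations (s).
#' @param area Observed area per video (um^2).
#' @param seed Integer seed.
#' @return List: `event_times` (pooled, s), `windows`, `area`, `truth`.
#' @export
gen_formation_events <- function(rate0, decay, windows, area, seed = 1L) {
  stopifnot(rate0 >= 0, decay >= 0, all(windows > 0), area > 0)
  set.seed(seed)
  times <- unlist(lapply(windows, function(Tw) {
    # expected count over the window, then inverse-CDF placement
    mu <- if (decay > 0) area * rate0 * (1 - exp(-decay * Tw)) / decay
          else area * rate0 * Tw
    n <- rpois(1, mu)
    if (n == 0) return(numeric(0))
    u <- runif(n)
    if (decay > 0) -log(1 - u * (1 - exp(-decay * Tw))) / decay else u * Tw
  }))
  list(event_times = sort(times), windows = windows, area = area,
       truth = .truth(rate0 = rate0, decay = decay, seed = seed))
}

#' Generate two-state FRET intensity traces
#'
#' Per trace: a lognormal total spot intensity; a two-state continuous-time
#' Markov path (low/high FRET) sampled at the frame times; donor and
#' acceptor channels split the total as `(1 - E)` and `E`; Gaussian
#' shot-like noise with sd proportional to the square root of the channel
#' intensity; optional single-step bleach truncation.
#'
#' @param n_traces,n_frames Trace count and length (frames).
#' @param state_rates `(k_low_to_high, k_high_to_low)` in s^-1.
#' @param E_states `(E_low, E_high)` FRET efficiencies in (0, 1).
#' @param total_intensity_log_mean,total_intensity_log_sd Lognormal
#'   parameters of the per-trace total intensity.
#' @param bleach_rate Single-step bleach rate (s^-1; 0 disables).
#' @param noise_scale Noise sd multiplier on `sqrt(intensity)`.
#' @param frame_interval Frame time (s).
#' @param start_state Initial state (`"low"`, `"high"` or `"stationary"`).
#' @param seed Integer seed.
#' @return List of class `fret_trace_set`: `traces` (list of data frames
#'   with frame, donor, acceptor, state), `truth`.
#' @export
gen_fret_intensity_traces <- function(n_traces, n_frames,
                                      state_rates = c(2, 10),
                                      E_states = c(0.5, 0.95),
                                      total_intensity_log_mean = log(500),
                                      total_intensity_log_sd = 0.3,
                                      bleach_rate = 0, noise_scale = 0.5,
                                      frame_interval = 0.030,
                                      start_state = "stationary",
                                      seed = 1L) {
  stopifnot(all(state_rates >= 0), all(E_states > 0), all(E_states < 1))
  set.seed(seed)
  k_lh <- state_rates[1]; k_hl <- state_rates[2]
  p_start_high <- switch(start_state,
                         low = 0, high = 1,
                         stationary = if (k_lh + k_hl > 0) {
                           k_lh / (k_lh + k_hl)
                         } else 0)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    total <- rlnorm(1, total_intensity_log_mean, total_intensity_log_sd)
    # exact CTMC path sampled at frame times
    state <- integer(n_frames)  # 0 low, 1 high
    s <- rbinom(1, 1, p_start_high)
    t_now <- 0
    t_next <- if ((s == 0 && k_lh == 0) || (s == 1 && k_hl == 0)) Inf
              else rexp(1, if (s == 0) k_lh else k_hl)
    for (f in seq_len(n_frames)) {
      tf <- (f - 1) * frame_interval
      while (t_now + t_next <= tf) {
        t_now <- t_now + t_next
        s <- 1L - s
        t_next <- if ((s == 0 && k_lh == 0) || (s == 1 && k_hl == 0)) Inf
                  else rexp(1, if (s == 0) k_lh else k_hl)
      }
      state[f] <- s
    }
    E <- ifelse(state == 1L, E_states[2], E_states[1])
    don <- (1 - E) * total
    acc <- E * total
    if (noise_scale > 0) {
      don <- don + rnorm(n_frames, 0, noise_scale * sqrt(pmax(don, 1)))
      acc <- acc + rnorm(n_frames, 0, noise_scale * sqrt(pmax(acc, 1)))
    }
    keep <- n_frames
    if (bleach_rate > 0) {
      tb <- rexp(1, bleach_rate)
      keep <- min(n_frames, max(1L, floor(tb / frame_interval)))
    }
    traces[[i]] <- data.frame(frame = seq_len(keep) - 1L,
                              donor = don[seq_len(keep)],
                              acceptor = acc[seq_len(keep)],
                              state = state[seq_len(keep)])
  }
  structure(list(traces = traces,
                 truth = .truth(state_rates = state_rates,
                                E_states = E_states,
                                total_intensity_log_mean =
                                  total_intensity_log_mean,
                                total_intensity_log_sd =
                                  total_intensity_log_sd,
                                bleach_rate = bleach_rate,
                                noise_scale = noise_scale,
                                frame_interval = frame_interval,
                                seed = seed)),
            class = "fret_trace_set")
}

#' Generate a synthetic interface-model matrix and experimental vector
#'
#' Model efficiency vectors are drawn uniformly per site and checked for
#' conditioning (collinear draws are rejected and redrawn); the synthetic
#' experimental vector is the simplex combination of a chosen true subset
#' plus Gaussian noise.
#'
#' @param m_models,n_sites Matrix dimensions.
#' @param true_subset Indices (or names) of the generating models.
#' @param true_coefficients Simplex weights of the generating models.
#' @param noise_sd Gaussian noise sd on the experimental vector.
#' @param seed Integer seed.
#' @param max_kappa Maximum accepted condition number of the model matrix.
#' @return List: `models` (sites x models matrix), `experimental`, `truth`.
#' @export
gen_interface_dataset <- function(m_models = 7, n_sites = 8,
                                  true_subset = c(1, 2),
                                  true_coefficients = c(0.8, 0.2),
                                  noise_sd = 0.05, seed = 1L,
                                  max_kappa = 50) {
  stopifnot(length(true_subset) == length(true_coefficients),
            abs(sum(true_coefficients) - 1) < 1e-9,
            all(true_coefficients >= 0))
  set.seed(seed)
  redraws <- 0L
  repeat {
    M <- matrix(runif(n_sites * m_models, 0.05, 0.95), n_sites, m_models)
    if (kappa(M, exact = TRUE) <= max_kappa) break
    redraws <- redraws + 1L
    if (redraws > 100) stop("could not draw a well-conditioned model matrix")
  }
  colnames(M) <- paste0("model_", seq_len(m_models))
  rownames(M) <- paste0("site_", seq_len(n_sites))
  if (is.character(true_subset)) true_subset <- match(true_subset,
                                                      colnames(M))
  y <- as.numeric(M[, true_subset, drop = FALSE] %*% true_coefficients) +
    rnorm(n_sites, 0, noise_sd)
  names(y) <- rownames(M)
  list(models = M, experimental = y,
       truth = .truth(true_subset = colnames(M)[true_subset],
                      true_coefficients = true_coefficients,
                      noise_sd = noise_sd, seed = seed,
                      redraws = redraws))
}

#' Generate DEER-style distance distributions
#'
#' The "experimental" distribution is a normalised Gaussian mixture on the
#' distance grid; the single components are returned as the candidate model
#' distributions.
#'
#' @param component_means,component_sds Component locations/widths (nm).
#' @param weights Mixture weights (simplex).
#' @param grid Distance grid (nm).
#' @param noise_sd Optional Gaussian noise added to the mixture density
#'   before renormalisation.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return List: `experimental` ([distance_distribution()]), `components`
#'   (list of distributions), `truth`.
#' @export
gen_deer_dataset <- function(component_means, component_sds, weights,
                             grid = seq(1.5, 8, by = 0.05), noise_sd = 0,
                             seed = 1L) {
  stopifnot(length(component_means) == length(component_sds),
            length(weights) == length(component_means),
            abs(sum(weights) - 1) < 1e-9)
  comps <- lapply(seq_along(component_means), function(i) {
    distance_distribution(grid, dnorm(grid, component_means[i],
                                      component_sds[i]),
                          label = paste0("component_", i))
  })
  names(comps) <- paste0("component_", seq_along(comps))
  dens <- Reduce(`+`, Map(function(w, d) w * d$density, weights, comps))
  if (noise_sd > 0) {
    set.seed(seed)
    dens <- pmax(dens + rnorm(length(grid), 0, noise_sd), 0)
  }
  list(experimental = distance_distribution(grid, dens, label = "mixture"),
       components = comps,
       truth = .truth(component_means = component_means,
                      component_sds = component_sds, weights = weights,
                      noise_sd = noise_sd, seed = seed))
}

#' Generate a noisy Gaussian emission spectrum
#'
#' Small helper for spectrum-processing tests: a Gaussian emission band on a
#' regular wavelength grid plus optional white noise.
#'
#' @param peak_nm,width_nm Band location and sd (nm).
#' @param amplitude Peak amplitude.
#' @param grid Wavelength grid (nm).
#' @param noise_sd White noise sd.
#' @param seed Integer seed.
#' @return An [emission_spectrum()] (`mixed`, donor excitation).
#' @export
gen_emission_spectrum <- function(peak_nm = 570, width_nm = 15,
                                  amplitude = 1000,
                                  grid = seq(500, 700, by = 1),
                                  noise_sd = 0, seed = 1L) {
  v <- amplitude * exp(-(grid - peak_nm)^2 / (2 * width_nm^2))
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(grid), 0, noise_sd)
  }
  emission_spectrum(grid, v, "donor", "mixed")
}
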