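# Shared in-code fixtures.

# cheap "large receptor" geometry: same dynamics, ~100x coarser time step,
# so equilibration is reachable in milliseconds of wall time
cheap_sim_config <- function(n_particles = 100, density = 10,
                             p_collision = 0.05, k_off = 1, duration = 5,
                             seed = 1L) {
  sim_config(n_particles = n_particles, density = density, D_mon = 1,
             D_dim = 0.8, radius = 0.025, p_collision = p_collision,
             k_off = k_off, dT = max_timestep(1, 0.05), duration = duration,
             seed = seed)
}

# a sim_trace built directly from count series (for estimator contracts)
fake_trace <- function(n_monomer, n_dimer, dt = 1) {
  n <- length(n_monomer)
  structure(list(times = seq_len(n) * dt, n_monomer = n_monomer,
                 n_dimer = n_dimer, n_collisions = rep(0L, n),
                 n_associations = rep(0L, n), total_associations = NA,
                 total_dissociations = NA, integral_mm1_dt = NA,
                 config = NULL, sample_every = 1L, frames = NULL,
                 equilibrium_start_index = 1L, equilibrated = TRUE),
            class = "sim_trace")
}

# msd_curve object from exact values
fake_msd <- function(lags, msd, se = rep(1e-6, length(lags))) {
  structure(list(lags = lags, msd = msd, weighted_sd = se * 2, se = se,
                 n_tracks = rep(100L, length(lags)),
                 n_pairs = rep(1000L, length(lags))),
            class = "msd_curve")
}
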