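#!/usr/bin/env Rscript
# Monomer-dimer dynamics of a membrane receptor: calibrate the 2D particle
# simulator to the experimentally measured kinetics (k_on = 0.081 um^2/s,
# k_off = 0.58 /s) and map the equilibrium dimer population across receptor
# densities, from single-molecule (0.43 um^-2) through physiological
# (2-40 um^-2) to ensemble (10^3 um^-2) conditions. The particle model is
# cross-checked against the analytic mass-action equilibrium and an exact
# well-mixed Gillespie simulation.
#
# Writes results/dimer_fraction_vs_density.csv and results/rates.json.
# Runtime: roughly 10 minutes on one core (dominated by the low-density
# simulations; edit `densities`/`seeds` to trade precision for time).

library(gpcrdimer)

dir.create("results", showWarnings = FALSE)
seed <- 1L

base <- sim_config(n_particles = 100, density = 0.43, p_collision = 0.01,
                   k_off = 0.58, dT = max_timestep(1.63, 0.005),
                   duration = 1, seed = seed)
message("calibrating p to k_on = 0.081 um^2/s ...")
cal <- calibrate_collision_probability(0.081, base, tol = 0.05,
                                       seed = seed + 90L, n_reps = 2)
message(sprintf("  p = %.4g per overlap step; achieved k_on = %.4g um^2/s",
                cal$p_collision, cal$achieved_k_on))

densities <- c(0.43, 2, 10, 40, 100, 1000)
rows <- lapply(densities, function(dens) {
  np <- if (dens >= 100) 300 else if (dens >= 10) 150 else 100
  dur <- if (dens >= 100) 2.5 else if (dens >= 10) 8 else 16
  burn <- dur / 4
  fr <- vapply(seed + 0:1, function(s) {
    cfg <- sim_config(n_particles = np, density = dens,
                      p_collision = cal$p_collision, k_off = 0.58,
                      dT = base$dT, duration = dur, seed = s)
    tr <- suppressWarnings(run_simulation(cfg))
    dimer_fraction(tr, burn_in = which(tr$times >= burn)[1])$fraction
  }, numeric(1))
  ma <- mass_action_equilibrium(cal$achieved_k_on, 0.58, dens)
  g <- gillespie_well_mixed(cal$achieved_k_on, 0.58, dens,
                            area = max(2 / dens * 100, 3),
                            t_max = max(60, 40 / (0.58)), seed = seed)
  dg <- dimer_fraction(g)
  message(sprintf("  density %8.2f: MC %.3f | mass action %.3f | SSA %.3f",
                  dens, mean(fr), ma$dimer_receptor_fraction, dg$fraction))
  data.frame(density = dens, mc_fraction = mean(fr),
             mass_action_fraction = ma$dimer_receptor_fraction,
             gillespie_fraction = dg$fraction)
})
sweep <- do.call(rbind, rows)
write.csv(sweep, "results/dimer_fraction_vs_density.csv", row.names = FALSE)

rates <- derive_rate_constants(k_on = 0.081, k_off = 0.58)
write_result_json(c(unclass(rates),
                    list(p_collision = cal$p_collision,
                         achieved_k_on = cal$achieved_k_on,
                         dimer_pct_at_0.43 =
                           100 * sweep$mc_fraction[sweep$density == 0.43],
                         dimer_pct_at_1000 =
                           100 * sweep$mc_fraction[sweep$density == 1000])),
                  "results/rates.json")
message("the dimer population is tuneable across the physiological range: ",
        sprintf("%.0f%% at 0.43 um^-2 rising to %.0f%% at 10^3 um^-2",
                100 * sweep$mc_fraction[1],
                100 * sweep$mc_fraction[nrow(sweep)]))
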