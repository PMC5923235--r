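# Particle simulator: step statistics, conservation, equilibria, oracles.

test_that("default and maximal time steps follow the rms-step rules", {
  expect_equal(default_timestep(1.63, 0.0025), 2.396472e-7,
               tolerance = 1e-6)
  # quadrupling D quarters the step at fixed radius
  expect_equal(default_timestep(4 * 1.2, 0.003),
               default_timestep(1.2, 0.003) / 4)
  # rms step at the maximal dT equals half the collision diameter
  dT <- max_timestep(1.63, 0.005)
  expect_equal(sqrt(4 * 1.63 * dT), 0.005 / 2)
  expect_error(default_timestep(1.63, 0), "positive")
  expect_error(default_timestep(-1, 0.0025), "positive")
})

test_that("sim_config validates geometry and step size", {
  cfg <- sim_config(n_particles = 100, density = 4, p_collision = 0.1,
                    k_off = 1, duration = 1)
  expect_equal(cfg$box_side, 5)
  expect_equal(cfg$collision_diameter, 2 * cfg$radius)
  expect_error(sim_config(100, 4, p_collision = 1.5, k_off = 1,
                          duration = 1), "p_collision")
  expect_error(sim_config(100, -1, p_collision = 0.5, k_off = 1,
                          duration = 1), "density")
  expect_error(sim_config(100, 4, p_collision = 0.5, k_off = 1,
                          dT = 1, duration = 1), "too coarse")
})

test_that("per-axis displacements are Gaussian with variance 2 D dT", {
  cfg <- cheap_sim_config(p_collision = 0, k_off = 0)
  n <- 5e4
  set.seed(1)
  box <- 50
  ens <- particle_ensemble(runif(n, 0, box), runif(n, 0, box),
                           rep("monomer", n), box_side = box)
  ens2 <- advance_ensemble(ens, cfg)
  dx <- (ens2$x - ens$x)
  dx <- dx - box * round(dx / box)  # unwrap
  v_target <- 2 * cfg$D_mon * cfg$dT
  expect_equal(var(dx), v_target, tolerance = 0.03)
  expect_gt(stats::shapiro.test(dx[1:5000])$p.value, 1e-3)
})

test_that("overlapping monomers dimerise and receptors are conserved", {
  # freeze diffusion so the pair stays inside contact for the trial
  cfg <- sim_config(n_particles = 2, density = 0.5, D_mon = 1e-8,
                    D_dim = 1e-8, radius = 0.025, p_collision = 1,
                    k_off = 0, dT = 1e-4, duration = 1)
  ens <- particle_ensemble(c(1, 1.001), c(1, 1), rep("monomer", 2),
                           box_side = cfg$box_side)
  set.seed(2)
  ens2 <- advance_ensemble(ens, cfg)
  expect_equal(length(ens2$x), 1L)
  expect_equal(ens2$species, "dimer")
  expect_equal(receptor_count(ens2), receptor_count(ens))
  expect_equal(sort(c(ens2$id1, ens2$id2)), c(1L, 2L))
})

test_that("per-step dissociation probability is 1 - exp(-k_off dT)", {
  dT <- max_timestep(1, 0.05)
  k_off <- 0.01 / dT  # so k_off * dT = 0.01
  cfg <- sim_config(n_particles = 2, density = 0.001, D_mon = 1,
                    D_dim = 0.8, radius = 0.025, p_collision = 0,
                    k_off = k_off, dT = dT, duration = 1)
  n <- 2e4
  box <- 1000
  set.seed(3)
  ens <- particle_ensemble(runif(n, 0, box), runif(n, 0, box),
                           rep("dimer", n), id1 = seq_len(n),
                           id2 = seq_len(n) + n, box_side = box)
  ens2 <- advance_ensemble(ens, cfg)
  n_diss <- (length(ens2$x) - n)
  p_hat <- n_diss / n
  p_true <- 1 - exp(-0.01)  # 0.00995
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  expect_equal(receptor_count(ens2), 2L * n)
})

test_that("dissociated monomers are re-placed just outside contact", {
  cfg <- cheap_sim_config(p_collision = 0, k_off = 1e5)
  set.seed(4)
  ens <- particle_ensemble(1, 1, "dimer", id1 = 1L, id2 = 2L,
                           box_side = cfg$box_side)
  # k_off huge so dissociation is certain this step
  ens2 <- advance_ensemble(ens, cfg)
  expect_equal(length(ens2$x), 2L)
  d <- sqrt(diff(ens2$x)^2 + diff(ens2$y)^2)
  expect_equal(d, cfg$collision_diameter * (1 + cfg$position_tolerance),
               tolerance = 1e-9)
})

test_that("run_simulation conserves receptors and is seed-deterministic", {
  cfg <- cheap_sim_config(duration = 2, seed = 9)
  tr <- run_simulation(cfg)
  expect_true(all(tr$n_monomer + 2L * tr$n_dimer == cfg$n_particles))
  tr2 <- run_simulation(sim_config(
    n_particles = cfg$n_particles, density = cfg$density, D_mon = cfg$D_mon,
    D_dim = cfg$D_dim, radius = cfg$radius, p_collision = cfg$p_collision,
    k_off = cfg$k_off, dT = cfg$dT, duration = cfg$duration, seed = 9))
  expect_identical(tr$n_dimer, tr2$n_dimer)
  expect_identical(tr$n_monomer, tr2$n_monomer)
})

test_that("no collisions are accepted when p_collision is zero", {
  cfg <- cheap_sim_config(p_collision = 0, k_off = 1, duration = 1)
  tr <- suppressWarnings(run_simulation(cfg))
  expect_true(all(tr$n_dimer == 0L))
})

test_that("with p = 1 and no dissociation all receptors end dimeric", {
  cfg <- cheap_sim_config(n_particles = 20, density = 50, p_collision = 1,
                          k_off = 0, duration = 5, seed = 5)
  tr <- suppressWarnings(run_simulation(cfg))
  expect_equal(tail(tr$n_dimer, 1), 10L)
  expect_equal(tail(tr$n_monomer, 1), 0L)
})

test_that("dimer_fraction handles pure and mixed traces", {
  expect_equal(dimer_fraction(fake_trace(rep(10L, 50), rep(0L, 50)),
                              burn_in = 1)$fraction, 0)
  expect_equal(dimer_fraction(fake_trace(rep(0L, 50), rep(5L, 50)),
                              burn_in = 1)$fraction, 1)
  # alternating 50/50 monomer-receptor / dimer-receptor split
  tr <- fake_trace(rep(10L, 40), rep(5L, 40))
  expect_equal(dimer_fraction(tr, burn_in = 2)$fraction, 0.5)
  expect_error(dimer_fraction(tr, burn_in = 40), "no samples")
})

test_that("mass-action equilibrium solves the quadratic", {
  r <- mass_action_equilibrium(0.081, 0.58, 0.43)
  expect_equal(r$dimer_receptor_fraction, 0.0977671, tolerance = 1e-6)
  expect_equal(r$K_d, 0.58 / 0.081)
  expect_equal(r$monomer_density + 2 * r$dimer_density, 0.43)
  r2 <- mass_action_equilibrium(0.081, 0.58, 1000)
  expect_equal(r2$dimer_receptor_fraction, 0.941928, tolerance = 1e-6)
  expect_equal(mass_action_equilibrium(0, 0.58, 5)$dimer_receptor_fraction,
               0)
  expect_error(mass_action_equilibrium(-1, 0.58, 5), "k_on")
})

test_that("Gillespie oracle matches mass action and is intensive", {
  expect_error(gillespie_well_mixed(0.1, 1, 10, 10, t_max = 0), "t_max")
  tr0 <- gillespie_well_mixed(0, 1, 10, 20, t_max = 5, seed = 1)
  expect_true(all(tr0$n_dimer == 0))

  ma <- mass_action_equilibrium(0.1, 1, 20)
  tr <- gillespie_well_mixed(0.1, 1, 20, area = 25, t_max = 150, seed = 2)
  df <- dimer_fraction(tr, burn_in = which(tr$times > 5)[1])
  expect_lt(abs(df$fraction - ma$dimer_receptor_fraction), 3 * df$se)
  # receptor conservation
  expect_true(all(tr$n_monomer + 2 * tr$n_dimer ==
                    tr$n_monomer[1] + 2 * tr$n_dimer[1]))
  # doubling the area at fixed densities leaves the fraction unchanged
  tr2 <- gillespie_well_mixed(0.1, 1, 20, area = 50, t_max = 150, seed = 3)
  df2 <- dimer_fraction(tr2, burn_in = which(tr2$times > 5)[1])
  expect_lt(abs(df2$fraction - df$fraction),
            3 * sqrt(df$se^2 + df2$se^2) + 0.02)
})

test_that("calibration hits a target k_on and is monotone in the target", {
  cfg <- cheap_sim_config()
  expect_equal(calibrate_collision_probability(0, cfg)$p_collision, 0)
  cal1 <- calibrate_collision_probability(
    0.1, cfg, tol = 0.15, seed = 21, density = 10, n_particles = 150,
    t_run = 1.0, n_reps = 2)
  expect_false(cal1$capped)
  # attainment up to the stated tolerance plus the event-count noise
  expect_lt(abs(cal1$achieved_k_on - 0.1),
            0.15 * 0.1 + 2 * cal1$achieved_k_on_se)
  cal2 <- calibrate_collision_probability(
    0.3, cfg, tol = 0.15, seed = 21, density = 10, n_particles = 150,
    t_run = 1.0, n_reps = 2)
  expect_gt(cal2$p_collision, cal1$p_collision)
})

test_that("calibrated simulator equilibrium matches both oracles", {
  # detailed-balance check in the cheap geometry at one density
  cfg <- cheap_sim_config(n_particles = 120, density = 10, k_off = 2,
                          duration = 12, seed = 31)
  cal <- calibrate_collision_probability(0.1, cfg, tol = 0.05, seed = 22,
                                         density = 10, n_particles = 150,
                                         t_run = 1.0)
  cfg <- cheap_sim_config(n_particles = 120, density = 10,
                          p_collision = cal$p_collision, k_off = 2,
                          duration = 12, seed = 31)
  tr <- suppressWarnings(run_simulation(cfg))
  df <- dimer_fraction(tr, burn_in = which(tr$times >= 3)[1])
  ma <- mass_action_equilibrium(cal$achieved_k_on, 2, 10)
  g <- gillespie_well_mixed(cal$achieved_k_on, 2, 10, area = 12,
                            t_max = 150, seed = 8)
  dg <- dimer_fraction(g, burn_in = which(g$times > 5)[1])
  expect_lt(abs(df$fraction - ma$dimer_receptor_fraction),
            3 * df$se + 0.01)
  expect_lt(abs(df$fraction - dg$fraction),
            3 * sqrt(df$se^2 + dg$se^2) + 0.01)
})

test_that("equilibrium detection flags unequilibrated runs", {
  cfg <- cheap_sim_config(n_particles = 60, density = 10, p_collision = 0.2,
                          k_off = 0.05, duration = 0.5, seed = 6)
  tr <- run_simulation(cfg, equil_window = 2000)
  expect_false(tr$equilibrated)
  expect_true(is.na(tr$equilibrium_start_index))
})
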