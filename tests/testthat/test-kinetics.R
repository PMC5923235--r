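# MSD/diffusion estimation, collision frequency, formation-rate
# extrapolation and derived constants.

test_that("MSD handles degenerate motion exactly", {
  # stationary particles
  df <- data.frame(track_id = rep(1:3, each = 5), frame = rep(0:4, 3),
                   x_um = rep(c(0, 1, 2), each = 5),
                   y_um = rep(c(0, -1, 4), each = 5))
  m <- msd_curve(track_table(df), max_lag = 3)
  expect_equal(m$msd, rep(0, 3))
  # ballistic straight-line track: MSD(tau) = (v tau)^2
  v <- 2  # um/s
  dt <- 0.03
  df2 <- data.frame(track_id = 1L, frame = 0:19, x_um = v * dt * (0:19),
                    y_um = 0)
  m2 <- msd_curve(track_table(df2, frame_interval = dt), max_lag = 4)
  expect_equal(m2$msd, (v * m2$lags)^2, tolerance = 1e-12)
  expect_error(msd_curve(track_table(df[0, ], validate_length = FALSE)),
               "empty")
})

test_that("diffusion fitting recovers generating coefficients", {
  # exact line msd = 4 * 2 * tau
  curve <- fake_msd(lags = (1:8) * 0.03, msd = 4 * 2 * (1:8) * 0.03)
  fit <- fit_diffusion(curve, n_fit_lags = 4)
  expect_equal(fit$D, 2, tolerance = 1e-9)
  expect_false(fit$negative)

  # synthetic Brownian tracks at the acceptor-channel coefficient
  tt <- gen_brownian_tracks(3000, D = 1.27, mean_length = 12, seed = 5)
  fit2 <- fit_diffusion(msd_curve(tt, max_lag = 8), n_fit_lags = 4)
  expect_gt(1.27, fit2$ci[1])
  expect_lt(1.27, fit2$ci[2])

  # localisation noise shows up as the intercept 4 sigma^2
  sig <- 0.05
  tt3 <- gen_brownian_tracks(4000, D = 1.63, mean_length = 15,
                             loc_noise = sig, seed = 6)
  fit3 <- fit_diffusion(msd_curve(tt3, max_lag = 8), n_fit_lags = 6,
                        with_offset = TRUE)
  # each coordinate difference carries 2 sigma^2 of noise variance, per axis
  expect_equal(fit3$intercept, 4 * sig^2, tolerance = 0.25)
  expect_error(fit_diffusion(fake_msd((1:4) * 0.03, rep(1, 4)),
                             n_fit_lags = 1), "at least 2")
})

test_that("MSD estimator is unbiased over replicates", {
  est <- vapply(1:50, function(s) {
    tt <- gen_brownian_tracks(250, D = 1.63, mean_length = 12, seed = s)
    fit_diffusion(msd_curve(tt, max_lag = 8), n_fit_lags = 4)$D
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.63) / 1.63, 0.02)
  # no-noise intercept consistent with zero
  tt <- gen_brownian_tracks(3000, D = 1.63, mean_length = 12, seed = 99)
  fit <- fit_diffusion(msd_curve(tt, max_lag = 8), n_fit_lags = 6,
                       with_offset = TRUE)
  # small relative to the lag-1 MSD (~0.2 um^2); per-lag correlations make
  # the nominal intercept SE unreliable for a sharp 2-SE bound
  expect_lt(abs(fit$intercept), 0.012)
})

test_that("diffusion comparison reproduces the z statistic and SD ratio", {
  same <- compare_diffusion(1.5, c(1.4, 1.6), 1.5, c(1.4, 1.6),
                            r1 = 0.0025, sd_length = 0.02)
  expect_equal(same$z, 0)
  expect_equal(same$radius_ratio, 1)

  # donor vs acceptor channel estimates
  cmp <- compare_diffusion(1.63, c(1.609, 1.647), 1.27, c(1.222, 1.317),
                           r1 = 0.0025, sd_length = 0.02)
  expect_equal(cmp$z, -13.79, tolerance = 1e-3)
  expect_lt(cmp$p, 1e-5)
  cmp2 <- compare_diffusion(1, c(0.99, 1.01), 0.779, c(0.77, 0.79),
                            r1 = 0.0025, sd_length = 0.02)
  expect_equal(cmp2$radius_ratio, 1.3937, tolerance = 1e-3)
  expect_error(compare_diffusion(1, c(0.9, 1.1), 0.01, c(0.005, 0.015),
                                 r1 = 0.0025, sd_length = 0.003),
               "range|exceed")
})

test_that("Hardt collision frequency follows the dilute capture-time form", {
  expect_equal(hardt_collision_frequency(0.43, 3.26, 0.005), 0.4305815,
               tolerance = 1e-6)
  # linear in D_rel
  expect_equal(hardt_collision_frequency(0.43, 2 * 3.26, 0.005),
               2 * hardt_collision_frequency(0.43, 3.26, 0.005))
  # vanishes in the dilute limit
  expect_lt(hardt_collision_frequency(1e-6, 3.26, 0.005),
            hardt_collision_frequency(0.43, 3.26, 0.005) * 1e-4)
  expect_error(hardt_collision_frequency(1e6, 3.26, 0.005), "dilute")
})

test_that("formation-rate extrapolation recovers generated kinetics", {
  # constant rate with fixed lambda = 0 equals the empirical mean exactly
  ev <- gen_formation_events(0.02, 0, windows = rep(6, 10), area = 100,
                             seed = 3)
  fit0 <- extrapolate_formation_rate(ev$event_times, ev$windows, 100,
                                     fix_lambda = 0)
  expect_equal(fit0$rate_at_t0,
               length(ev$event_times) / (100 * sum(ev$windows)),
               tolerance = 1e-12)

  # decaying rate: A and lambda recovered within their 95% CIs (most seeds)
  hit <- vapply(1:10, function(s) {
    ev <- gen_formation_events(0.02, 0.5, windows = rep(6, 40), area = 100,
                               seed = s)
    fit <- extrapolate_formation_rate(ev$event_times, ev$windows, 100)
    fit$rate_ci[1] <= 0.02 && 0.02 <= fit$rate_ci[2]
  }, logical(1))
  expect_gte(mean(hit), 0.7)
  expect_error(extrapolate_formation_rate(numeric(0), rep(6, 5), 100),
               "no events")
  expect_error(extrapolate_formation_rate(rep(0.1, 30), rep(6, 5), 100,
                                          bin_width = 0.5),
               "fewer than 2")
})

test_that("labelling correction divides by the visible pair fraction", {
  expect_equal(correct_for_labelling(1, 0.5, 0.5), 2)
  expect_equal(correct_for_labelling(0, 0.3, 0.6), 0)
  # 100:405:45 donor:acceptor:unlabelled
  f <- c(100, 405, 45) / 550
  expect_equal(2 * f[1] * f[2], 0.26777, tolerance = 1e-4)
  expect_equal(correct_for_labelling(0.0217, f[1], f[2]),
               0.0217 / (2 * f[1] * f[2]))
  expect_error(correct_for_labelling(1, 0, 0.5), "zero")
  expect_error(correct_for_labelling(1, 0.6, 0.6))
})

test_that("derived constants reproduce the printed equilibrium values", {
  # measured equilibrium: 9.8% dimeric receptors at 0.43 um^-2
  rs <- derive_rate_constants(equilibrium = c(0.098, 0.43))
  expect_equal(signif(rs$K_d, 2), 7.1)
  # measured k_off fixes the half-life
  rs2 <- derive_rate_constants(k_off = 0.58)
  expect_equal(signif(rs2$t_half, 2), 1.2)
  expect_equal(derive_rate_constants(k_off = log(2))$t_half, 1)
  # round trip through the mass-action oracle: K_d = k_off / k_on to 1e-6
  ma <- mass_action_equilibrium(0.2, 1.5, 30)
  rt <- derive_rate_constants(k_off = 1.5,
                              equilibrium = c(ma$dimer_receptor_fraction,
                                              30))
  expect_equal(rt$K_d, 1.5 / 0.2, tolerance = 1e-6)
  expect_equal(rt$k_on, 0.2, tolerance = 1e-6)
  expect_error(derive_rate_constants(k_on = 0.1, k_off = 1,
                                     equilibrium = c(0.2, 10)),
               "inconsistent")
})
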