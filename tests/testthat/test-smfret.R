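# Log-intensity mixture models, bootstrap BIC, threshold dwell analysis and
# per-frame efficiencies.

test_that("single-component fit equals the closed-form lognormal MLE", {
  set.seed(10)
  x <- rlnorm(2000, log(200), 0.3)
  fit <- fit_log_intensity_mixture(x, k_range = 1)$models$k1
  z <- log(x)
  mu_hat <- mean(z)
  sd_hat <- sqrt(mean((z - mu_hat)^2))
  expect_equal(fit$means, mu_hat, tolerance = 1e-6)
  expect_equal(fit$sds, sd_hat, tolerance = 1e-6)
  ll <- sum(dnorm(z, mu_hat, sd_hat, log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$bic, 2 * ll - 2 * log(2000), tolerance = 1e-8)
})

test_that("two lognormal components are recovered at the observed mixing", {
  # high/low FRET split of the dimer acceptor intensities: 84/16
  set.seed(11)
  n <- 5000
  low <- rlnorm(round(0.84 * n), log(100), 0.25)
  high <- rlnorm(n - round(0.84 * n), log(100) + 4 * 0.25, 0.25)
  fit <- fit_log_intensity_mixture(c(low, high), k_range = 1:2)
  expect_equal(fit$best_k, 2L)
  m2 <- fit$models$k2
  expect_equal(sum(m2$weights), 1, tolerance = 1e-9)
  expect_lt(abs(m2$weights[1] - 0.84), 0.05)
  expect_lt(abs(m2$weights[2] - 0.16), 0.05)
  # EM log-likelihood is non-decreasing along the accepted run
  expect_true(all(diff(m2$loglik_trace) > -1e-6 * abs(m2$loglik)))
})

test_that("EM agrees with an independent mixture implementation", {
  suppressPackageStartupMessages(library(mclust))
  set.seed(12)
  x <- c(rlnorm(1500, log(80), 0.2), rlnorm(500, log(400), 0.3))
  ours <- fit_log_intensity_mixture(x, k_range = 2)$models$k2
  ref <- mclust::Mclust(log(x), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-4)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 1e-3)
})

test_that("bootstrap BIC prefers the generating component count", {
  set.seed(13)
  x <- rlnorm(5000, log(150), 0.3)
  fit <- fit_log_intensity_mixture(x, k_range = 1:3, n_boot = 60,
                                   boot_size = 1000, seed = 2)
  # delta BIC is <= 0 by construction, with 0 at each replicate's best k
  expect_true(all(fit$boot_delta_bic <= 1e-9, na.rm = TRUE))
  expect_true(all(apply(fit$boot_delta_bic, 1, max, na.rm = TRUE) == 0))
  expect_gte(mean(fit$boot_best_k == 1), 0.95)
  expect_error(fit_log_intensity_mixture(c(-1, x)), "positive")
  expect_error(fit_log_intensity_mixture(x, n_boot = 5, boot_size = 1e6),
               "boot_size")
  expect_error(fit_log_intensity_mixture(rep(100, 50), k_range = 2),
               "unique")
})

test_that("the high-state threshold is the low-state tail quantile", {
  th <- high_state_threshold(log(100), 0.2, 0.01)
  expect_equal(th$threshold, 159.244, tolerance = 1e-4)
  # P(X >= threshold) = tail_prob under the low-state lognormal
  expect_equal(plnorm(th$threshold, log(100), 0.2, lower.tail = FALSE),
               0.01, tolerance = 1e-9)
  # degenerate width collapses to the median
  expect_equal(high_state_threshold(log(50), 1e-12, 0.01)$threshold, 50,
               tolerance = 1e-6)
  expect_equal(high_state_threshold(log(70), 0.3, 0.4999)$threshold, 70,
               tolerance = 1e-3)
  expect_error(high_state_threshold(log(100), 0.2, 0.7), "tail_prob")
})

test_that("dwell segmentation enumerates runs with position classes", {
  # states L,L,H,L,L,L at 30 ms
  seg <- segment_dwells(c(1, 1, 5, 1, 1, 1), threshold = 3,
                        frame_interval = 0.03)
  d <- seg$dwells
  expect_equal(d$state, c("low", "high", "low"))
  expect_equal(d$duration_s, c(0.06, 0.03, 0.09))
  expect_equal(d$class, c("initial", "mid", "final"))
  expect_false(any(d$censored))
  # dwells tile the trajectory exactly
  expect_equal(sum(d$n_frames), 6)

  all_low <- segment_dwells(rep(1, 10), threshold = 3)
  expect_true(all_low$dwells$censored)
  expect_length(all_low$survival, 0)
  expect_error(segment_dwells(numeric(0), 3), "empty")
  expect_error(segment_dwells(c(1, 2), 3), "3 frames")
})

test_that("survival curves are proper complementary CDFs", {
  set.seed(14)
  traces <- replicate(60, rlnorm(30, log(100), 0.8), simplify = FALSE)
  dw <- do.call(rbind, lapply(traces, function(x) {
    segment_dwells(x, threshold = 120)$dwells
  }))
  sc <- survival_curves(dw)
  expect_gt(length(sc), 0)
  for (s in sc) {
    expect_equal(s$survival[1], 1)
    expect_true(all(diff(s$survival) <= 0))
    expect_gte(min(s$survival), 0)
  }
})

test_that("two-state Markov exchange rates are recovered from dwells", {
  ts <- gen_fret_intensity_traces(150, 400, state_rates = c(2, 10),
                                  E_states = c(0.5, 0.95),
                                  noise_scale = 0, seed = 15)
  thr <- high_state_threshold(log(mean(sapply(ts$traces, function(t) {
    mean(t$acceptor[t$state == 0])
  }))), 1e-6, 0.01)
  dw <- do.call(rbind, lapply(ts$traces, function(tr) {
    segment_dwells(tr$acceptor, thr, 0.03)$dwells
  }))
  rates <- dwell_rates(dw, 0.03)
  expect_gt(sum(rates$n_dwells), 500)
  k_low <- rates$exit_rate[rates$state == "low"]    # = k_low->high
  k_high <- rates$exit_rate[rates$state == "high"]  # = k_high->low
  expect_lt(abs(1 / k_low - 1 / 2) / (1 / 2), 0.10)
  expect_lt(abs(1 / k_high - 1 / 10) / (1 / 10), 0.10)
})

test_that("per-frame efficiency, histogram and high-FRET fraction", {
  ff <- frame_fret_efficiency(donor = c(100, 0, 50),
                              acceptor = c(100, 80, 150), gamma = 1)
  expect_equal(ff$efficiency, c(0.5, 1, 0.75))
  expect_equal(ff$n_excluded, 0)
  # zero-total frames are flagged and excluded
  ff2 <- frame_fret_efficiency(c(0, 100), c(0, 100))
  expect_equal(ff2$n_excluded, 1)
  expect_true(is.na(ff2$efficiency[1]))

  # 20% of frames in a high state at E = 0.95 against E_low = 0.5
  ts <- gen_fret_intensity_traces(200, 200, state_rates = c(2.5, 10),
                                  E_states = c(0.5, 0.95),
                                  noise_scale = 0.5, seed = 16)
  don <- unlist(lapply(ts$traces, `[[`, "donor"))
  acc <- unlist(lapply(ts$traces, `[[`, "acceptor"))
  st <- unlist(lapply(ts$traces, `[[`, "state"))
  ff3 <- frame_fret_efficiency(don, acc, gamma = 1, cutoff = 0.9)
  expect_lt(abs(ff3$fraction_above - mean(st)), 0.03)
  expect_lt(abs(ff3$fraction_above - 0.2), 0.04)
  expect_equal(sum(ff3$histogram$count),
               length(don) - ff3$n_excluded)
})
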