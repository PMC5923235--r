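# Simplex-constrained combination fitting, AIC ranking, F-tests, DEER.

test_that("model efficiency vectors average per-frame efficiencies", {
  v <- model_efficiency_vector(list(TM1 = c(7, 7), TM4 = 7), R0 = 7)
  expect_equal(unname(v), c(0.5, 0.5))
  expect_equal(unname(model_efficiency_vector(list(s = 4.6), R0 = 7)),
               0.92547, tolerance = 1e-4)
  # idempotent averaging: {R0, R0} equals {R0}
  expect_equal(model_efficiency_vector(list(a = c(6, 6))),
               model_efficiency_vector(list(a = 6)))
  # for spread samples in the convex tail, averaging efficiencies gives a
  # lower value than converting the mean distance
  spread <- list(a = c(3, 9))
  expect_lt(model_efficiency_vector(spread)[1],
            model_efficiency_vector(spread, average = "mean_distance")[1])
  expect_error(model_efficiency_vector(list(a = c(-1, 5))), "positive")
  expect_error(model_efficiency_vector(list()), "no sites")
})

test_that("simplex fit satisfies its constraints and exact cases", {
  ds <- gen_interface_dataset(m_models = 4, n_sites = 8, noise_sd = 0,
                              true_subset = 1, true_coefficients = 1,
                              seed = 20)
  # y equals one model exactly
  fit <- fit_combination(ds$models[, 1], ds$models)
  expect_equal(unname(fit$coefficients["model_1"]), 1, tolerance = 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  # constraint contract on arbitrary targets
  set.seed(21)
  for (i in 1:5) {
    y <- runif(8)
    f <- fit_combination(y, ds$models)
    expect_equal(sum(f$coefficients), 1, tolerance = 1e-9)
    expect_true(all(f$coefficients >= -1e-12))
  }
})

test_that("simplex fit matches an independent dense grid search", {
  ds <- gen_interface_dataset(m_models = 3, n_sites = 8, noise_sd = 0.1,
                              true_subset = c(1, 2),
                              true_coefficients = c(0.6, 0.4), seed = 22)
  fit <- fit_combination(ds$experimental, ds$models)
  # brute-force oracle: all simplex points on a fine grid
  step <- 0.005
  g <- seq(0, 1, by = step)
  best <- Inf; best_c <- NULL
  for (c1 in g) for (c2 in seq(0, 1 - c1, by = step)) {
    cc <- c(c1, c2, 1 - c1 - c2)
    rss <- sum((ds$experimental - ds$models %*% cc)^2)
    if (rss < best) { best <- rss; best_c <- cc }
  }
  expect_lte(fit$rss, best + 1e-12)
  expect_lt(max(abs(fit$coefficients - best_c)), 2 * step)
})

test_that("noise-free mixtures are recovered exactly, noisy ones loosely", {
  ds0 <- gen_interface_dataset(m_models = 5, n_sites = 8, noise_sd = 0,
                               true_subset = c(2, 4),
                               true_coefficients = c(0.7, 0.3), seed = 23)
  f0 <- fit_combination(ds0$experimental, ds0$models,
                        subset = c("model_2", "model_4"))
  expect_equal(unname(f0$coefficients), c(0.7, 0.3), tolerance = 1e-6)

  # noise sd 0.05: recovery within +-0.15 (generating pair known)
  ok <- vapply(1:10, function(s) {
    ds <- gen_interface_dataset(m_models = 4, n_sites = 8, noise_sd = 0.05,
                                true_subset = c(1, 2),
                                true_coefficients = c(0.8, 0.2), seed = s)
    f <- fit_combination(ds$experimental, ds$models,
                         subset = c("model_1", "model_2"))
    all(abs(f$coefficients - c(0.8, 0.2)) <= 0.15)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("fits are invariant to consistent site reordering", {
  ds <- gen_interface_dataset(m_models = 4, n_sites = 8, noise_sd = 0.05,
                              seed = 24)
  f1 <- fit_combination(ds$experimental, ds$models)
  perm <- sample(8)
  f2 <- fit_combination(ds$experimental[perm], ds$models[perm, ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-12)
})

test_that("duplicated models are flagged as non-identifiable", {
  ds <- gen_interface_dataset(m_models = 3, n_sites = 8, seed = 25)
  M <- cbind(ds$models, model_3b = ds$models[, 3])
  f <- fit_combination(ds$experimental, M)
  expect_true(f$non_identifiable)
})

test_that("subset enumeration ranks all combinations by AIC", {
  ds <- gen_interface_dataset(m_models = 7, n_sites = 8, noise_sd = 0.05,
                              seed = 26)
  rk <- enumerate_subsets(ds$experimental, ds$models)
  expect_equal(nrow(rk$table), 127L)  # 2^7 - 1 combinations
  expect_equal(rk$table$delta_aic[1], 0)
  expect_true(all(diff(rk$table$aic) >= 0))
  ds1 <- gen_interface_dataset(m_models = 1, n_sites = 8,
                               true_subset = 1, true_coefficients = 1,
                               seed = 27)
  expect_equal(nrow(enumerate_subsets(ds1$experimental,
                                      ds1$models)$table), 1L)
})

test_that("adding a model to a subset never increases the RSS", {
  ds <- gen_interface_dataset(m_models = 5, n_sites = 8, noise_sd = 0.1,
                              seed = 28)
  rk <- enumerate_subsets(ds$experimental, ds$models)
  tab <- rk$table
  for (i in seq_len(nrow(tab))) {
    inner <- strsplit(tab$subset[i], "+", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(tab))) {
      outer <- strsplit(tab$subset[j], "+", fixed = TRUE)[[1]]
      if (length(outer) == length(inner) + 1 && all(inner %in% outer)) {
        expect_lte(tab$rss[j], tab$rss[i] + 1e-10)
      }
    }
  }
})

test_that("AIC recognises the generating models in most replicates", {
  res <- t(vapply(1:30, function(s) {
    ds <- gen_interface_dataset(m_models = 5, n_sites = 8, noise_sd = 0.05,
                                true_subset = c(1, 3),
                                true_coefficients = c(0.6, 0.4), seed = s)
    rk <- enumerate_subsets(ds$experimental, ds$models)
    c(exact = setequal(rk$best$subset, c("model_1", "model_3")),
      contained = all(c("model_1", "model_3") %in% rk$best$subset))
  }, logical(2)))
  # the AIC penalty (2 per model) admits one spurious component with ~8%
  # probability each, capping the exact-pair rate well below the
  # containment rate
  expect_gte(mean(res[, "contained"]), 0.9)
  expect_gte(mean(res[, "exact"]), 0.6)
})

test_that("the nested F-test behaves at its degenerate and shifted poles", {
  ds <- gen_interface_dataset(m_models = 3, n_sites = 8, noise_sd = 0.05,
                              true_subset = c(1, 2),
                              true_coefficients = c(0.8, 0.2), seed = 30)
  y <- ds$experimental
  # identical conditions: separate fits equal the pooled one
  pooled <- fit_combination(c(y, y), rbind(ds$models, ds$models),
                            subset = c("model_1", "model_2"))
  sep <- list(fit_combination(y, ds$models, c("model_1", "model_2")),
              fit_combination(y, ds$models, c("model_1", "model_2")))
  ft <- nested_f_test(pooled, sep)
  expect_lt(abs(ft$F), 1e-6)
  expect_gt(ft$p, 0.999)

  # shifted coefficients between conditions become detectable
  sig <- vapply(1:10, function(s) {
    d1 <- gen_interface_dataset(m_models = 3, n_sites = 8, noise_sd = 0.02,
                                true_subset = c(1, 2),
                                true_coefficients = c(0.8, 0.2), seed = s)
    y2 <- as.numeric(d1$models[, c(1, 2)] %*% c(0.7, 0.3)) +
      rnorm(8, 0, 0.02)
    pooled <- fit_combination(c(d1$experimental, y2),
                              rbind(d1$models, d1$models),
                              subset = c("model_1", "model_2"))
    sep <- list(fit_combination(d1$experimental, d1$models,
                                c("model_1", "model_2")),
                fit_combination(y2, d1$models, c("model_1", "model_2")))
    nested_f_test(pooled, sep)$p < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.6)

  # single-model subsets add no parameters
  p1 <- fit_combination(c(y, y), rbind(ds$models, ds$models), "model_1")
  s1 <- list(fit_combination(y, ds$models, "model_1"),
             fit_combination(y, ds$models, "model_1"))
  expect_error(nested_f_test(p1, s1), "df1")
  expect_error(nested_f_test(pooled, s1), "share")
})

test_that("DEER combination fitting recovers mixture weights", {
  dd <- gen_deer_dataset(component_means = c(2.5, 5.5),
                         component_sds = c(0.4, 0.5),
                         weights = c(0.6, 0.4))
  # experimental equal to one component
  f1 <- fit_deer_combination(dd$components[[1]], dd$components)
  expect_equal(unname(f1$coefficients), c(1, 0), tolerance = 1e-8)
  expect_lt(f1$rss, 1e-12)

  f <- fit_deer_combination(dd$experimental, dd$components)
  expect_equal(unname(f$coefficients), c(0.6, 0.4), tolerance = 0.05)
  # fitted combination integrates to 1
  g <- f$distribution
  expect_equal(sum(diff(g$r_nm) * (head(g$density, -1) +
                                     tail(g$density, -1)) / 2), 1,
               tolerance = 1e-6)
  far <- distance_distribution(seq(10, 12, 0.05),
                               dnorm(seq(10, 12, 0.05), 11, 0.2))
  expect_error(fit_deer_combination(far, dd$components), "overlap")
})
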