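# Simplex-constrained combination fitting of candidate dimer-interface
# models against per-site FRET efficiency vectors and DEER distance
# distributions, with AIC ranking and nested F-tests.

#' Predicted per-site FRET efficiency vector of a structural model
#'
#' Converts per-site distance samples (e.g. label-site distances measured
#' along a simulation trajectory) to the model's expected efficiency per
#' site, as the mean over samples of `E(R) = R0^6/(R0^6 + R^6)`. Averaging
#' per-frame efficiencies (rather than converting the mean distance)
#' reflects that energy transfer averages over the conformational ensemble.
#'
#' @param distance_samples Named list, one numeric vector of distances (nm)
#'   per labelling site.
#' @param R0 Forster radius (nm).
#' @param average One of `"per_frame"` (mean of efficiencies, default) or
#'   `"mean_distance"` (efficiency of the mean distance).
#' @return Named numeric efficiency vector (one entry per site).
#' @export
model_efficiency_vector <- function(distance_samples, R0 = 7.0,
                                    average = c("per_frame",
                                                "mean_distance")) {
  average <- match.arg(average)
  if (length(distance_samples) == 0) stop("no sites supplied")
  vapply(distance_samples, function(r) {
    if (length(r) == 0) stop("each site needs at least one distance sample")
    if (any(r <= 0)) stop("distances must be positive")
    if (average == "per_frame") {
      mean(efficiency_distance_conversion(r, "to_efficiency", R0))
    } else {
      efficiency_distance_conversion(mean(r), "to_efficiency", R0)
    }
  }, numeric(1))
}

# Exact solver for min ||y - X c||^2 with c >= 0, sum(c) = 1, by exhaustive
# enumeration of active sets (every zero-pattern's equality-constrained
# solution is a candidate; the optimum is the feasible candidate of minimal
# RSS). Exact and fast for the <= 7 models arising here.
.simplex_ls <- function(y, X) {
  m <- ncol(X)
  best <- NULL
  for (mask in seq_len(2^m) - 1L) {
    free <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (length(free) == 0) next
    Xf <- X[, free, drop = FALSE]
    q <- length(free)
    A <- rbind(cbind(crossprod(Xf), rep(1, q)), c(rep(1, q), 0))
    b <- c(crossprod(Xf, y), 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    cf <- sol[seq_len(q)]
    if (any(cf < -1e-9)) next
    cf[cf < 0] <- 0
    cfull <- numeric(m)
    cfull[free] <- cf / sum(cf)
    rss <- sum((y - X %*% cfull)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(coefficients = cfull, rss = rss)
    }
  }
  if (is.null(best)) stop("simplex-constrained fit failed (singular models)")
  best
}

#' Fit a simplex-constrained linear combination of model vectors
#'
#' Finds the fractional contributions `c_i >= 0`, `sum c_i = 1`, of the
#' chosen models that minimise the residual sum of squares against the
#' experimental efficiency vector. Reports
#' `AIC = n ln(RSS/n) + 2 k` with `k` the subset size ((k - 1) free
#' coefficients plus the residual variance); lower AIC indicates the more
#' probable model.
#'
#' @param experimental Named numeric vector of per-site efficiencies.
#' @param models Numeric matrix, sites x models (column names are model
#'   names), or a named list of vectors.
#' @param subset Model names or column indices to include (default: all).
#' @param sems Optional per-site standard errors; when supplied the fit is
#'   weighted (rows scaled by `1/sem`). Default is the unweighted fit.
#' @return Object of class `combination_fit`: `subset`, `coefficients`,
#'   `rss`, `aic`, `n_points`, `non_identifiable` flag.
#' @export
fit_combination <- function(experimental, models, subset = NULL,
                            sems = NULL) {
  if (is.list(models) && !is.matrix(models)) {
    models <- do.call(cbind, models)
  }
  stopifnot(is.matrix(models), length(experimental) == nrow(models))
  if (is.null(colnames(models))) {
    colnames(models) <- paste0("model_", seq_len(ncol(models)))
  }
  if (is.null(subset)) subset <- colnames(models)
  if (is.numeric(subset)) subset <- colnames(models)[subset]
  if (length(subset) == 0) stop("`subset` must name at least one model")
  X <- models[, subset, drop = FALSE]
  y <- as.numeric(experimental)
  if (!is.null(sems)) {
    stopifnot(length(sems) == length(y), all(sems > 0))
    y <- y / sems
    X <- X / sems
  }
  dup <- anyDuplicated(t(X)) > 0
  fit <- .simplex_ls(y, X)
  n <- length(y)
  k <- length(subset)
  aic <- n * log(fit$rss / n) + 2 * k
  structure(list(subset = subset,
                 coefficients = setNames(fit$coefficients, subset),
                 rss = fit$rss, aic = aic, n_points = n,
                 weighted = !is.null(sems), non_identifiable = dup),
            class = "combination_fit")
}

#' @export
print.combination_fit <- function(x, ...) {
  cat(sprintf("combination fit over {%s}\n", paste(x$subset, collapse = ", ")))
  cat("  coefficients:",
      paste(sprintf("%s=%.3f", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  RSS %.4g, AIC %.3f (n = %d)\n", x$rss, x$aic, x$n_points))
  if (x$non_identifiable) cat("  note: duplicated models in subset\n")
  invisible(x)
}

#' Fit and rank every non-empty model subset
#'
#' Fits all `2^m - 1` simplex-constrained combinations of the `m` models and
#' ranks them by AIC (ascending), reporting the AIC difference to the best
#' subset.
#'
#' @inheritParams fit_combination
#' @return List of class `subset_ranking`: `fits` (ranked list of
#'   [fit_combination()] results), `table` (data frame: subset, size, rss,
#'   aic, delta_aic), `best`.
#' @export
enumerate_subsets <- function(experimental, models, sems = NULL) {
  if (is.list(models) && !is.matrix(models)) models <- do.call(cbind, models)
  if (is.null(colnames(models))) {
    colnames(models) <- paste0("model_", seq_len(ncol(models)))
  }
  m <- ncol(models)
  stopifnot(m >= 1, m <= 7)
  nm <- colnames(models)
  subsets <- unlist(lapply(seq_len(m), function(s) {
    asplit(utils::combn(nm, s), 2)
  }), recursive = FALSE)
  fits <- lapply(subsets, function(s) {
    fit_combination(experimental, models, subset = s, sems = sems)
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  o <- order(aics)
  fits <- fits[o]
  tab <- data.frame(
    subset = vapply(fits, function(f) paste(f$subset, collapse = "+"),
                    character(1)),
    size = vapply(fits, function(f) length(f$subset), integer(1)),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  tab$delta_aic <- tab$aic - tab$aic[1]
  structure(list(fits = fits, table = tab, best = fits[[1]]),
            class = "subset_ranking")
}

#' @export
print.subset_ranking <- function(x, n = 8, ...) {
  cat(sprintf("%d subset fits; best: %s (AIC %.2f)\n", nrow(x$table),
              x$table$subset[1], x$table$aic[1]))
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}

#' Nested F-test comparing a pooled fit against per-condition fits
#'
#' Tests whether fitting the two conditions separately (with the same model
#' subset) significantly improves on a single pooled coefficient set:
#' `F = ((RSS_pooled - RSS_sep)/dk) / (RSS_sep/(n - k_sep))` with
#' `RSS_sep` the summed separate residuals and `dk` the extra parameters.
#'
#' @param fit_pooled [fit_combination()] over the stacked conditions.
#' @param fits_separate List of per-condition [fit_combination()] results on
#'   the same subset.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
nested_f_test <- function(fit_pooled, fits_separate) {
  stopifnot(inherits(fit_pooled, "combination_fit"))
  subs <- lapply(fits_separate, `[[`, "subset")
  if (!all(vapply(subs, identical, logical(1), fit_pooled$subset))) {
    stop("pooled and separate fits must share the model subset")
  }
  rss_sep <- sum(vapply(fits_separate, `[[`, numeric(1), "rss"))
  n <- sum(vapply(fits_separate, `[[`, numeric(1), "n_points"))
  k_one <- length(fit_pooled$subset) - 1  # free coefficients per fit
  k_sep <- k_one * length(fits_separate)
  df1 <- k_sep - k_one
  if (df1 <= 0) stop("separate fits add no free parameters (df1 = 0)")
  df2 <- n - k_sep
  if (rss_sep <= 0) {
    warning("separate fits are exact; p-value degenerates to 0")
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  Fst <- ((fit_pooled$rss - rss_sep) / df1) / (rss_sep / df2)
  list(F = Fst, p = pf(Fst, df1, df2, lower.tail = FALSE), df1 = df1,
       df2 = df2)
}

#' Distance distribution container
#'
#' @param r_nm Ascending distance grid (nm).
#' @param density Non-negative probability density values.
#' @param label Optional label.
#' @param normalise Renormalise so the trapezoidal integral is 1.
#' @return Data frame of class `distance_distribution`.
#' @export
distance_distribution <- function(r_nm, density, label = NULL,
                                  normalise = TRUE) {
  stopifnot(length(r_nm) == length(density), all(diff(r_nm) > 0))
  if (any(density < 0)) stop("densities must be non-negative")
  if (normalise) {
    z <- .trapz(r_nm, density)
    if (z <= 0) stop("distribution has zero mass")
    density <- density / z
  }
  structure(data.frame(r_nm = r_nm, density = density),
            label = label, class = c("distance_distribution", "data.frame"))
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Fit a DEER distance distribution as a combination of model distributions
#'
#' Resamples the experimental and model distributions onto a common grid
#' (linear interpolation) restricted to a distance window, then applies the
#' same simplex-constrained least squares as [fit_combination()] to the
#' binned densities; the fitted combination is renormalised. The window
#' default reflects that inter-label distances in a receptor dimer are
#' expected within 1.5-8 nm while long distances are poorly determined.
#'
#' @param experimental A [distance_distribution()].
#' @param model_dists List of model [distance_distribution()]s.
#' @param subset Names/indices of models to include (default all).
#' @param r_window Fit window in nm.
#' @param grid_step Common grid step (nm); defaults to the finest input step.
#' @return A `combination_fit` with the fitted `distribution` attached.
#' @export
fit_deer_combination <- function(experimental, model_dists, subset = NULL,
                                 r_window = c(1.5, 8), grid_step = NULL) {
  stopifnot(inherits(experimental, "distance_distribution"))
  if (is.null(names(model_dists))) {
    names(model_dists) <- paste0("model_", seq_along(model_dists))
  }
  lo <- max(min(experimental$r_nm), r_window[1],
            vapply(model_dists, function(d) min(d$r_nm), numeric(1)))
  hi <- min(max(experimental$r_nm), r_window[2],
            vapply(model_dists, function(d) max(d$r_nm), numeric(1)))
  if (hi <= lo) stop("distance distributions do not overlap inside the window")
  if (is.null(grid_step)) {
    grid_step <- min(vapply(c(list(experimental), model_dists),
                            function(d) median(diff(d$r_nm)), numeric(1)))
  }
  grid <- seq(lo, hi, by = grid_step)
  y <- approx(experimental$r_nm, experimental$density, grid)$y
  X <- vapply(model_dists, function(d) approx(d$r_nm, d$density, grid)$y,
              numeric(length(grid)))
  fit <- fit_combination(y, X, subset = subset)
  comb <- as.numeric(X[, fit$subset, drop = FALSE] %*% fit$coefficients)
  fit$distribution <- distance_distribution(grid, pmax(comb, 0),
                                            label = "fitted combination")
  fit
}
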