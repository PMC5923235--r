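# Diffusion and kinetic-constant estimation from single-particle track tables.

#' Mean squared displacement curve from a track table
#'
#' Computes the per-track MSD at each time lag using all displacement pairs
#' (overlapping windows), then combines tracks as a weighted average with
#' weights equal to the number of displacement pairs each track contributes
#' at that lag. The weighted standard deviation is taken over per-track MSD
#' values; the standard error divides it by the square root of the number of
#' contributing tracks.
#'
#' @param tracks A [track_table()].
#' @param max_lag Maximum lag in frames.
#' @return Object of class `msd_curve` with `lags` (s), `msd` (um^2),
#'   `weighted_sd`, `se`, `n_tracks`, `n_pairs` per lag.
#' @export
msd_curve <- function(tracks, max_lag = 10L) {
  stopifnot(inherits(tracks, "track_table"), max_lag >= 1)
  dt <- attr(tracks, "frame_interval")
  ids <- unique(tracks$track_id)
  if (length(ids) == 0) stop("empty track table")
  # per-track, per-lag sums of squared displacements
  sum_sq <- matrix(0, length(ids), max_lag)
  n_pairs <- matrix(0L, length(ids), max_lag)
  by_track <- split(tracks[c("frame", "x_um", "y_um")], tracks$track_id)
  for (k in seq_along(by_track)) {
    tr <- by_track[[k]]
    o <- order(tr$frame)
    fr <- tr$frame[o]; xs <- tr$x_um[o]; ys <- tr$y_um[o]
    n <- length(fr)
    if (n < 2) next
    for (lag in seq_len(min(max_lag, n - 1))) {
      # pair frames exactly `lag` frames apart (robust to gaps)
      j <- match(fr + lag, fr)
      ok <- !is.na(j)
      if (!any(ok)) next
      d2 <- (xs[j[ok]] - xs[ok])^2 + (ys[j[ok]] - ys[ok])^2
      sum_sq[k, lag] <- sum(d2)
      n_pairs[k, lag] <- length(d2)
    }
  }
  msd <- numeric(max_lag); wsd <- numeric(max_lag); se <- numeric(max_lag)
  ntr <- integer(max_lag)
  u <- matrix(0, length(ids), max_lag)     # normalised track weights
  dev <- matrix(0, length(ids), max_lag)   # per-track deviations
  for (lag in seq_len(max_lag)) {
    w <- n_pairs[, lag]
    use <- w > 0
    ntr[lag] <- sum(use)
    if (ntr[lag] == 0) {
      msd[lag] <- NA; wsd[lag] <- NA; se[lag] <- NA
      next
    }
    per_track <- sum_sq[use, lag] / w[use]
    ww <- w[use]
    m <- sum(ww * per_track) / sum(ww)
    msd[lag] <- m
    v <- sum(ww * (per_track - m)^2) / sum(ww)
    wsd[lag] <- sqrt(v)
    se[lag] <- wsd[lag] / sqrt(ntr[lag])
    u[use, lag] <- ww / sum(ww)
    dev[use, lag] <- per_track - m
  }
  # between-track covariance of the weighted mean MSD across lags: the same
  # tracks feed every lag, so per-lag estimates are strongly correlated and
  # any slope uncertainty must account for it
  cov_msd <- crossprod(u * dev)
  structure(list(lags = seq_len(max_lag) * dt, msd = msd, weighted_sd = wsd,
                 se = se, n_tracks = ntr,
                 n_pairs = colSums(n_pairs), cov_msd = cov_msd),
            class = "msd_curve")
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Weighted linear fit of `MSD = 4 D tau` (optionally with an intercept
#' `4 sigma_loc^2` absorbing static localisation noise) over the first
#' `n_fit_lags` lags, weights `1/se^2`. The confidence interval comes from
#' the fit covariance propagated through the between-track covariance of
#' the MSD curve (per-lag MSDs share tracks and are strongly correlated, so
#' a naive residual-based interval would be far too narrow).
#'
#' @param curve An [msd_curve()].
#' @param n_fit_lags Number of leading lags fitted; defaults to the first
#'   quarter of the curve (at least 2).
#' @param with_offset Include an intercept for localisation noise.
#' @return List of class `diffusion_fit`: `D`, `se`, `ci` (95\%),
#'   `intercept`/`sigma_loc_sq` (when `with_offset`), `negative` flag.
#' @export
fit_diffusion <- function(curve, n_fit_lags = NULL, with_offset = FALSE) {
  stopifnot(inherits(curve, "msd_curve"))
  if (is.null(n_fit_lags)) n_fit_lags <- max(2L, floor(length(curve$lags) / 4))
  if (n_fit_lags < 2) stop("`n_fit_lags` must be at least 2")
  idx <- seq_len(min(n_fit_lags, length(curve$lags)))
  ok <- idx[is.finite(curve$msd[idx])]
  if (length(ok) < 2) stop("fewer than 2 usable lags")
  tau <- curve$lags[ok]
  m <- curve$msd[ok]
  se_l <- curve$se[ok]
  w <- if (all(is.finite(se_l)) && all(se_l > 0)) 1 / se_l^2
       else rep(1, length(ok))
  X <- if (with_offset) cbind(1, tau) else cbind(tau)
  XtW <- t(X * w)
  A <- solve(XtW %*% X)          # (X'WX)^-1
  H <- A %*% XtW                 # beta = H m
  beta <- as.numeric(H %*% m)
  Sigma <- curve$cov_msd
  cov_beta <- if (!is.null(Sigma)) {
    H %*% Sigma[ok, ok, drop = FALSE] %*% t(H)
  } else {
    A  # fall back to the nominal GLS covariance
  }
  k <- if (with_offset) 2L else 1L
  slope <- beta[k]
  se_slope <- sqrt(cov_beta[k, k])
  D <- slope / 4
  se_D <- se_slope / 4
  out <- list(D = D, se = se_D, ci = D + c(-1, 1) * 1.96 * se_D,
              negative = D < 0, with_offset = with_offset,
              n_lags_used = length(ok))
  if (with_offset) {
    out$intercept <- beta[1]
    out$intercept_se <- sqrt(cov_beta[1, 1])
    out$sigma_loc_sq <- beta[1] / 4
  }
  if (D < 0) warning("fitted diffusion coefficient is negative")
  class(out) <- "diffusion_fit"
  out
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("D = %.4g um^2/s (95%% CI [%.4g, %.4g])\n",
              x$D, x$ci[1], x$ci[2]))
  if (x$with_offset) {
    cat(sprintf("  localisation noise sigma_loc^2 = %.3g um^2\n",
                x$sigma_loc_sq))
  }
  invisible(x)
}

#' Compare two diffusion coefficients and infer a hydrodynamic radius ratio
#'
#' The two estimates (with 95\% normal confidence intervals) are compared by
#' a two-sided z-test, `z = (D2 - D1)/sqrt(SE1^2 + SE2^2)` with
#' `SE = CI width / 3.92`. Under the Saffman-Delbrueck model,
#' `D` is proportional to `ln(L/r) - gamma` for an inclusion of radius `r`
#' and a characteristic (hydrodynamic) length `L`, so the radius ratio
#' solves `(ln(L/r2) - gamma) / (ln(L/r1) - gamma) = D2/D1` with Euler's
#' constant `gamma = 0.5772...`.
#'
#' @param D1,D2 Point estimates (um^2/s).
#' @param ci1,ci2 95\% confidence intervals, length-2.
#' @param r1 Radius of the first species (um).
#' @param sd_length Saffman-Delbrueck characteristic length `L` (um). No
#'   universally agreed value exists for a given bilayer; it must be given
#'   explicitly.
#' @return List with `z`, `p` (two-sided), `radius_ratio` (`r2/r1`), `r2`.
#' @export
compare_diffusion <- function(D1, ci1, D2, ci2, r1, sd_length) {
  stopifnot(length(ci1) == 2, length(ci2) == 2, r1 > 0, sd_length > 0)
  se1 <- (ci1[2] - ci1[1]) / 3.92
  se2 <- (ci2[2] - ci2[1]) / 3.92
  z <- (D2 - D1) / sqrt(se1^2 + se2^2)
  p <- 2 * pnorm(-abs(z))
  gamma_e <- 0.57721566490153286
  base <- log(sd_length / r1) - gamma_e
  if (base <= 0) {
    stop("`sd_length` must exceed r1 * exp(gamma) for the model to apply")
  }
  lhs <- (D2 / D1) * base  # = ln(L/r2) - gamma
  r2 <- sd_length / exp(lhs + gamma_e)
  if (r2 <= 0 || r2 >= sd_length) {
    stop("D2/D1 = ", signif(D2 / D1, 4), " is outside the solvable range ",
         "for L = ", sd_length, " um (inferred r2 = ", signif(r2, 4), " um)")
  }
  list(z = z, p = p, radius_ratio = r2 / r1, r2 = r2)
}

#' Mean monomer-monomer collision frequency (Hardt's dilute estimate)
#'
#' Mean capture time of a pair of diffusers in 2D at surface density `rho`:
#' `tau = b^2 (ln(b/a) - 3/4) / (2 D_rel)` with `b = (pi rho)^(-1/2)` the
#' half mean inter-particle distance and `a` the contact radius. The areal
#' collision frequency is `rho / (2 tau)` (pairwise, no double counting).
#'
#' @param density Receptor density (um^-2).
#' @param D_rel Relative diffusion coefficient of the pair (um^2/s); the sum
#'   of the two particles' coefficients for two mobile species.
#' @param contact_radius Capture radius (um).
#' @return Collision frequency in um^-2 s^-1.
#' @export
hardt_collision_frequency <- function(density, D_rel, contact_radius) {
  stopifnot(density > 0, D_rel > 0, contact_radius > 0)
  b <- 1 / sqrt(pi * density)
  if (b <= contact_radius) {
    stop("density too high for the dilute formula (b <= contact radius)")
  }
  tau <- b^2 * (log(b / contact_radius) - 0.75) / (2 * D_rel)
  density / (2 * tau)
}

#' Extrapolate the dimer-formation rate to zero photobleaching
#'
#' New-dimer appearance events are binned over time since illumination
#' start; the areal event rate per bin is fitted with an exponential decay
#' `rate(t) = A exp(-lambda t)` by least squares, so that `A` estimates the
#' formation rate before any photobleaching has depleted the visible pool.
#'
#' @param event_times Appearance times (s), pooled over videos, measured
#'   from each video's illumination start.
#' @param observation_windows Per-video observation durations (s).
#' @param area Observed area per video (um^2); scalar or per-video.
#' @param bin_width Bin width (s).
#' @param fix_lambda Optionally fix the decay constant (e.g. 0 for a
#'   constant-rate fit, in which case `rate_at_t0` is the plain mean binned
#'   rate).
#' @return List of class `formation_fit`: `rate_at_t0` (um^-2 s^-1) with
#'   `ci`, `bleach_decay` (s^-1) with `ci`, the binned `data`, and the fit.
#' @export
extrapolate_formation_rate <- function(event_times, observation_windows,
                                       area, bin_width = 0.5,
                                       fix_lambda = NULL) {
  if (length(event_times) == 0) stop("no events supplied")
  stopifnot(all(event_times >= 0), all(observation_windows > 0), all(area > 0))
  if (length(area) == 1) area <- rep(area, length(observation_windows))
  t_max <- max(observation_windows)
  breaks <- seq(0, t_max + bin_width, by = bin_width)
  mids <- head(breaks, -1) + bin_width / 2
  counts <- as.integer(table(cut(event_times, breaks, right = FALSE)))
  # exposure of each bin: area-time during which each video observed it
  expo <- vapply(seq_along(mids), function(b) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    sum(area * pmax(0, pmin(observation_windows, hi) - lo))
  }, numeric(1))
  keep <- expo > 0
  d <- data.frame(t = mids[keep], rate = counts[keep] / expo[keep],
                  count = counts[keep], exposure = expo[keep])
  if (is.null(fix_lambda) && sum(d$count > 0) < 2) {
    stop("events fall in fewer than 2 time bins; cannot fit a decay")
  }
  if (!is.null(fix_lambda)) {
    stopifnot(fix_lambda >= 0)
    x <- exp(-fix_lambda * d$t)
    A <- sum(d$rate * x) / sum(x^2)
    se_A <- sqrt(sum((d$rate - A * x)^2) / max(1, nrow(d) - 1) / sum(x^2))
    out <- list(rate_at_t0 = A, rate_ci = A + c(-1, 1) * 1.96 * se_A,
                bleach_decay = fix_lambda, decay_ci = c(fix_lambda,
                                                        fix_lambda),
                data = d, fit = NULL, n_events = length(event_times))
    class(out) <- "formation_fit"
    return(out)
  }
  # starting values from a log-linear fit on positive bins
  pos <- d$rate > 0
  st <- lm(log(rate) ~ t, data = d[pos, , drop = FALSE])
  start <- list(A = exp(coef(st)[[1]]), lambda = max(1e-6, -coef(st)[[2]]))
  fit1 <- tryCatch(
    nls(rate ~ A * exp(-lambda * t), data = d, start = start),
    error = function(e) {
      minpack.lm::nlsLM(rate ~ A * exp(-lambda * t), data = d, start = start)
    })
  # one reweighting pass: binned rates are counting-noise limited, with
  # variance proportional to the (fitted) rate over the bin exposure
  w <- d$exposure / pmax(stats::fitted(fit1), max(d$rate) * 1e-3)
  fit <- tryCatch(
    nls(rate ~ A * exp(-lambda * t), data = d, start = as.list(coef(fit1)),
        weights = w),
    error = function(e) fit1)
  cf <- coef(fit)
  vc <- vcov(fit)
  out <- list(
    rate_at_t0 = cf[["A"]],
    rate_ci = cf[["A"]] + c(-1, 1) * 1.96 * sqrt(vc["A", "A"]),
    bleach_decay = cf[["lambda"]],
    decay_ci = cf[["lambda"]] + c(-1, 1) * 1.96 * sqrt(vc["lambda", "lambda"]),
    data = d, fit = fit, n_events = length(event_times))
  class(out) <- "formation_fit"
  out
}

#' Correct an observed dimer-formation rate for the labelling ratio
#'
#' Only donor-acceptor pairs are FRET-visible; under random pairing the
#' visible fraction of dimers is `2 f_donor f_acceptor`.
#'
#' @param observed_rate Observed (FRET-visible) areal rate (um^-2 s^-1).
#' @param f_donor,f_acceptor Labelled fractions (sum with the unlabelled
#'   fraction to 1).
#' @return The total formation rate, `observed_rate / (2 f_donor f_acceptor)`.
#' @export
correct_for_labelling <- function(observed_rate, f_donor, f_acceptor) {
  stopifnot(f_donor >= 0, f_acceptor >= 0, f_donor + f_acceptor <= 1 + 1e-12)
  vis <- 2 * f_donor * f_acceptor
  if (vis <= 0) stop("visible fraction 2*f_donor*f_acceptor is zero")
  observed_rate / vis
}

#' Derive equilibrium and lifetime constants from rates or composition
#'
#' Combines whichever sufficient inputs are given: with both rate constants,
#' `K_d = k_off / k_on`; with an equilibrium composition (dimer receptor
#' fraction and total density), `K_d = M^2 / D` from the implied monomer and
#' dimer densities, and the missing rate constant follows from the one
#' supplied. The dimer half-life is `t_half = ln 2 / k_off`.
#'
#' @param k_on Association constant (um^2/s), optional.
#' @param k_off Dissociation rate (s^-1), optional.
#' @param equilibrium Optional list/vector `(dimer_fraction, total_density)`:
#'   fraction of receptors residing in dimers, and total density (um^-2).
#' @return Object of class `rate_set` with `k_on`, `k_off`, `K_d` (um^-2),
#'   `t_half` (s), and `areal_formation_rate` at the equilibrium composition
#'   when derivable.
#' @export
derive_rate_constants <- function(k_on = NULL, k_off = NULL,
                                  equilibrium = NULL) {
  have_rates <- !is.null(k_on) && !is.null(k_off)
  have_eq <- !is.null(equilibrium)
  if (!have_rates && !have_eq && is.null(k_off)) {
    stop("supply (k_on, k_off), or an equilibrium composition, or k_off")
  }
  K_d_eq <- NULL
  M <- D <- NULL
  if (have_eq) {
    eq <- unlist(equilibrium)
    frac <- eq[[1]]; rho <- eq[[2]]
    stopifnot(frac >= 0, frac <= 1, rho > 0)
    D <- frac * rho / 2
    M <- rho - 2 * D
    if (D <= 0) stop("equilibrium composition has no dimers; K_d undefined")
    K_d_eq <- M^2 / D
  }
  if (have_rates && have_eq) {
    K_d_rates <- k_off / k_on
    if (abs(K_d_rates - K_d_eq) > 1e-6 * K_d_eq) {
      stop("over-specified and inconsistent: K_d from rates = ",
           signif(K_d_rates, 6), " but from equilibrium composition = ",
           signif(K_d_eq, 6), " um^-2")
    }
  }
  if (have_eq) {
    K_d <- K_d_eq
    if (is.null(k_on) && !is.null(k_off)) k_on <- k_off / K_d
    if (is.null(k_off) && !is.null(k_on)) k_off <- k_on * K_d
  } else if (have_rates) {
    K_d <- k_off / k_on
  } else {
    K_d <- NA_real_  # a single rate constant fixes only the lifetime
  }
  out <- list(
    k_on = if (is.null(k_on)) NA_real_ else k_on,
    k_off = if (is.null(k_off)) NA_real_ else k_off,
    K_d = K_d,
    t_half = if (is.null(k_off)) NA_real_ else log(2) / k_off,
    areal_formation_rate = if (!is.null(k_on) && !is.null(M)) {
      k_on * M^2
    } else NA_real_)
  class(out) <- "rate_set"
  out
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Dimerisation rate set\n")
  cat(sprintf("  k_on  = %.4g um^2/s\n", x$k_on))
  cat(sprintf("  k_off = %.4g /s\n", x$k_off))
  cat(sprintf("  K_d   = %.4g um^-2\n", x$K_d))
  cat(sprintf("  t_1/2 = %.4g s\n", x$t_half))
  invisible(x)
}
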