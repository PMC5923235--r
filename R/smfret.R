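# Single-molecule intensity analytics: log-space Gaussian mixtures with
# bootstrap BIC, threshold construction, dwell/survival analysis and
# per-frame FRET efficiencies.

.em_1d <- function(z, k, means0, sds0, w0, tol = 1e-8, max_iter = 500L) {
  n <- length(z)
  mu <- means0; sg <- pmax(sds0, 1e-8); w <- w0 / sum(w0)
  sd_floor <- max(1e-6 * diff(range(z)), 1e-12)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step in log space for stability
    lg <- vapply(seq_len(k), function(j) {
      dnorm(z, mu[j], sg[j], log = TRUE) + log(w[j])
    }, numeric(n))
    if (k == 1) lg <- matrix(lg, ncol = 1)
    m <- apply(lg, 1, max)
    p <- exp(lg - m)
    rs <- rowSums(p)
    ll <- sum(m + log(rs))
    r <- p / rs
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)  # dead component, restart elsewhere
    w <- nk / n
    mu <- colSums(r * z) / nk
    sg <- pmax(sqrt(colSums(r * (z - rep(mu, each = n))^2) / nk), sd_floor)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sg, loglik = ll, n_iter = it,
       loglik_trace = ll_trace)
}

.em_init <- function(z, k, jitter_sd = 0) {
  qs <- quantile(z, probs = seq(0, 1, length.out = k + 1))
  grp <- cut(z, unique(c(-Inf, qs[-c(1, k + 1)], Inf)), labels = FALSE)
  if (length(unique(grp)) < k) grp <- sample.int(k, length(z), replace = TRUE)
  mu <- tapply(z, grp, mean)
  sg <- tapply(z, grp, sd)
  sg[is.na(sg) | sg == 0] <- sd(z) / k
  if (jitter_sd > 0) mu <- mu + rnorm(k, 0, jitter_sd)
  list(means = as.numeric(mu), sds = as.numeric(sg),
       w = as.numeric(table(factor(grp, levels = seq_len(k)))) + 1)
}

.fit_gmm_logspace <- function(z, k, n_restarts = 10L, tol = 1e-8,
                              max_iter = 500L) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- .em_init(z, k, jitter_sd = if (r == 1) 0 else sd(z) / 2)
    fit <- .em_1d(z, k, init$means, init$sds, init$w, tol, max_iter)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM failed for k = ", k)
  o <- order(best$means)
  best$means <- best$means[o]; best$sds <- best$sds[o]
  best$weights <- best$weights[o]
  best$k <- k
  best$n_params <- 3L * k - 1L
  # BIC on the "higher is better" convention: 2 lnL - p ln n
  best$bic <- 2 * best$loglik - best$n_params * log(length(z))
  best
}

#' Fit lognormal mixture models to single-molecule spot intensities
#'
#' Gaussian mixture models with 1 to 4 components are fitted by EM to the
#' logarithm of the spot intensities (so each component is a lognormal in
#' intensity space). Model probability is assessed by
#' `BIC = 2 lnL - p ln n` with `p = 3k - 1` parameters, on the convention
#' that higher BIC indicates the more probable model. To compare models on
#' equal footing across datasets of different size, the data can be
#' bootstrapped: each replicate resamples `boot_size` intensities, refits
#' every `k`, and reports the BIC difference to the replicate's best model
#' (`BIC_k - max_k BIC_k`, which is 0 for the winning `k` and negative
#' otherwise).
#'
#' @param intensities Positive spot intensities (camera counts).
#' @param k_range Component counts to fit (subset of 1:4 by default).
#' @param n_boot Number of bootstrap replicates (0 to skip).
#' @param boot_size Resample size per replicate (at most `n`).
#' @param seed Seed for restarts and bootstrap resampling.
#' @param n_restarts EM restarts for the full-data fits (bootstrap refits
#'   use `boot_restarts`).
#' @param boot_restarts Restarts per bootstrap refit.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return Object of class `log_mixture_set`: `models` (one fit per k, each
#'   with lognormal `weights`, `means`, `sds` on the log scale, `loglik`,
#'   `bic`), `best_k`, and when bootstrapped a `boot_delta_bic` matrix
#'   (replicates x k) plus `boot_best_k`.
#' @export
fit_log_intensity_mixture <- function(intensities, k_range = 1:4,
                                      n_boot = 0L, boot_size = 1000L,
                                      seed = 1L, n_restarts = 10L,
                                      boot_restarts = 2L, tol = 1e-8) {
  if (any(intensities <= 0)) stop("intensities must be positive")
  n <- length(intensities)
  if (n_boot > 0 && boot_size > n) {
    stop("`boot_size` exceeds the sample size")
  }
  if (length(unique(intensities)) < max(k_range)) {
    stop("fewer unique intensities than mixture components")
  }
  z <- log(intensities)
  set.seed(seed)
  models <- lapply(k_range, function(k) {
    .fit_gmm_logspace(z, k, n_restarts = n_restarts, tol = tol)
  })
  names(models) <- paste0("k", k_range)
  bics <- vapply(models, `[[`, numeric(1), "bic")
  out <- list(models = models, k_range = k_range,
              bic = bics, best_k = k_range[which.max(bics)], n = n)
  if (n_boot > 0) {
    delta <- matrix(NA_real_, n_boot, length(k_range),
                    dimnames = list(NULL, names(models)))
    for (b in seq_len(n_boot)) {
      zb <- z[sample.int(n, boot_size, replace = TRUE)]
      bb <- vapply(k_range, function(k) {
        fit <- tryCatch(
          .fit_gmm_logspace(zb, k, n_restarts = boot_restarts, tol = tol),
          error = function(e) NULL)
        if (is.null(fit)) NA_real_ else fit$bic
      }, numeric(1))
      delta[b, ] <- bb - max(bb, na.rm = TRUE)
    }
    out$boot_delta_bic <- delta
    out$boot_best_k <- k_range[apply(delta, 1, which.max)]
  }
  class(out) <- "log_mixture_set"
  out
}

#' @export
print.log_mixture_set <- function(x, ...) {
  cat(sprintf("log-intensity mixtures (n = %d): best k = %d\n", x$n,
              x$best_k))
  for (m in x$models) {
    cat(sprintf("  k=%d BIC %.1f  weights %s\n", m$k, m$bic,
                paste(signif(m$weights, 3), collapse = "/")))
  }
  invisible(x)
}

#' Conservative high-state intensity threshold
#'
#' The threshold above which an intensity has at most `tail_prob`
#' probability of belonging to the low-FRET state: the `1 - tail_prob`
#' quantile of the low state's lognormal,
#' `exp(log_mean + z_(1-tail_prob) * log_sd)`.
#'
#' @param log_mean,log_sd Low-state component parameters on the log scale.
#' @param tail_prob Allowed low-state exceedance probability.
#' @return List of class `threshold_spec`: `threshold` (counts),
#'   `tail_prob`, and the low-state parameters.
#' @export
high_state_threshold <- function(log_mean, log_sd, tail_prob = 0.01) {
  stopifnot(log_sd >= 0, tail_prob > 0, tail_prob < 0.5)
  structure(list(threshold = exp(log_mean + qnorm(1 - tail_prob) * log_sd),
                 tail_prob = tail_prob, log_mean = log_mean,
                 log_sd = log_sd),
            class = "threshold_spec")
}

#' Segment an intensity trace into high/low dwells
#'
#' Binarises the trace at the threshold; contiguous runs become dwells of
#' duration `run length x frame_interval`. Dwells are classed by position in
#' the trajectory (`initial`, `mid`, `final`); a run spanning the whole
#' trajectory is marked censored (its true duration is unknown in both
#' directions) and excluded from the survival curves. Survival curves are
#' the empirical complementary CDFs of dwell durations per state and class.
#'
#' @param trace Numeric intensity series (one trajectory), length >= 3.
#' @param threshold Counts threshold (or a [high_state_threshold()] result).
#' @param frame_interval Frame time (s).
#' @return List with `dwells` (data frame: state, n_frames, duration_s,
#'   class, censored) and `survival` (list of per state/class data frames
#'   with columns duration_s, survival).
#' @export
segment_dwells <- function(trace, threshold, frame_interval = 0.030) {
  if (length(trace) == 0) stop("empty trace")
  if (length(trace) < 3) stop("trace must span at least 3 frames")
  if (inherits(threshold, "threshold_spec")) threshold <- threshold$threshold
  states <- ifelse(trace > threshold, "high", "low")
  r <- rle(states)
  k <- length(r$lengths)
  cls <- rep("mid", k)
  if (k >= 1) cls[1] <- "initial"
  if (k >= 1) cls[k] <- "final"
  censored <- rep(FALSE, k)
  if (k == 1) censored[1] <- TRUE
  dwells <- data.frame(state = r$values, n_frames = r$lengths,
                       duration_s = r$lengths * frame_interval,
                       class = cls, censored = censored,
                       stringsAsFactors = FALSE)
  list(dwells = dwells, survival = survival_curves(dwells))
}

#' Empirical survival curves of dwell durations
#'
#' @param dwells A dwell data frame (possibly pooled over trajectories).
#' @return Named list (`state.class`) of data frames with `duration_s` and
#'   `survival = P(T > t)`; curves start at 1 and are non-increasing.
#' @export
survival_curves <- function(dwells) {
  d <- dwells[!dwells$censored, , drop = FALSE]
  if (nrow(d) == 0) return(list())
  groups <- split(d$duration_s, interaction(d$state, d$class, drop = TRUE))
  lapply(groups, function(x) {
    ts <- sort(unique(x))
    data.frame(duration_s = c(0, ts),
               survival = c(1, vapply(ts, function(t0) mean(x > t0),
                                      numeric(1))))
  })
}

#' State exchange rates from dwell durations
#'
#' Mean dwell durations are biased by frame discretisation: an exponential
#' dwell at rate `k` sampled on frames of length `dt` is observed as a
#' geometric number of frames with mean `1/(1 - exp(-k dt))`. Using
#' mid-trajectory dwells only (unbiased by truncation), the rate is
#' recovered by inverting that relation:
#' `k_hat = -log(1 - 1/mean_frames) / dt`.
#'
#' @param dwells Pooled dwell data frame from [segment_dwells()].
#' @param frame_interval Frame time (s).
#' @return Data frame per state: mean duration, mean frames, exit rate
#'   (s^-1), mean lifetime `1/k`, and the dwell count used.
#' @export
dwell_rates <- function(dwells, frame_interval = 0.030) {
  d <- dwells[!dwells$censored & dwells$class == "mid", , drop = FALSE]
  if (nrow(d) == 0) stop("no mid-trajectory dwells available")
  res <- lapply(split(d, d$state), function(g) {
    mf <- mean(g$n_frames)
    k <- if (mf > 1) -log(1 - 1 / mf) / frame_interval else Inf
    data.frame(state = g$state[1], n_dwells = nrow(g),
               mean_duration_s = mean(g$duration_s), mean_frames = mf,
               exit_rate = k, mean_lifetime_s = 1 / k)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-frame FRET efficiency from donor/acceptor intensity traces
#'
#' `E_t = I_A / (I_A + gamma I_D)` per frame; frames with non-positive
#' total intensity are flagged and excluded. Also reports a histogram over
#' `[0, 1]` and the fraction of frames above a cutoff.
#'
#' @param donor,acceptor Aligned intensity series (counts).
#' @param gamma Detection-correction factor (1 for raw counts).
#' @param cutoff High-FRET cutoff for the reported fraction.
#' @param bin_width Histogram bin width.
#' @return List with `efficiency` (NA at excluded frames), `histogram`
#'   (mids/counts/density), `fraction_above`, `n_excluded`.
#' @export
frame_fret_efficiency <- function(donor, acceptor, gamma = 1, cutoff = 0.9,
                                  bin_width = 0.05) {
  stopifnot(length(donor) == length(acceptor), gamma > 0)
  tot <- acceptor + gamma * donor
  bad <- !is.finite(tot) | tot <= 0
  E <- rep(NA_real_, length(tot))
  E[!bad] <- acceptor[!bad] / tot[!bad]
  Eh <- pmin(pmax(E[!bad], 0), 1)
  breaks <- seq(0, 1, by = bin_width)
  h <- hist(Eh, breaks = breaks, plot = FALSE)
  list(efficiency = E,
       histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density),
       fraction_above = mean(E[!bad] > cutoff),
       cutoff = cutoff, n_excluded = sum(bad))
}
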