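# Univariate quantitative-EEG features (complexity + continuity families).
# Each function takes one channel's samples (microvolts) and returns named
# numerics. Degenerate inputs (constant channels) return documented sentinel
# values, never NaN: downstream detectors require finite matrices.

.amplitude_hist <- function(x, n_bins, rng = range(x)) {
  if (rng[1] == rng[2]) return(1)           # single occupied bin
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, n_bins) / length(x)
  p[p > 0]
}

#' Shannon entropy of the amplitude distribution
#'
#' Entropy in bits of an equal-width amplitude histogram spanning
#' `[min(x), max(x)]`. A constant signal has zero entropy.
#'
#' @param x numeric samples (length >= 2).
#' @param n_bins number of histogram bins (default 64).
#' @param rng histogram support (defaults to the signal's own range).
#' @export
shannon_entropy <- function(x, n_bins = 64L, rng = range(x)) {
  p <- .amplitude_hist(x, n_bins, rng)
  -sum(p * log2(p))
}

#' Default Tsallis entropy orders
#' @export
tsallis_q_default <- c(1.1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 7, 10)

#' Tsallis entropies of the amplitude distribution
#'
#' Non-additive generalization of Shannon entropy,
#' `S_q = (1 - sum(p^q)) / (q - 1)`, computed on the same equal-width
#' amplitude histogram as [shannon_entropy()]. `q = 1` is evaluated as the
#' limit, i.e. Shannon entropy in nats.
#'
#' @param x numeric samples.
#' @param q_orders entropy orders (default: the package's 10-order grid).
#' @param n_bins histogram bins.
#' @return Named vector, one value per order.
#' @export
tsallis_entropies <- function(x, q_orders = tsallis_q_default, n_bins = 64L) {
  p <- .amplitude_hist(x, n_bins)
  vapply(q_orders, function(q) {
    if (abs(q - 1) < 1e-12) -sum(p * log(p))
    else (1 - sum(p^q)) / (q - 1)
  }, 0) |> stats::setNames(paste0("tsallis_q", q_orders))
}

#' Subband information quantity
#'
#' Shannon entropy (bits) of each frequency subband of a Daubechies-4 discrete
#' wavelet decomposition. The decomposition depth is chosen so the dyadic
#' subbands line up with the clinical bands at the working rate (delta 0-3,
#' theta 4-7, alpha 8-15, beta 16-31, gamma >= 32 Hz); gamma pools every
#' detail level above the beta subband. When `fs` is too low to resolve gamma
#' the highest available subband is used and flagged in the
#' `"gamma_fallback"` attribute.
#'
#' @param x numeric samples.
#' @param fs sampling rate, Hz.
#' @param n_bins histogram bins for the entropy of each subband.
#' @return Named 5-vector `iq_delta .. iq_gamma`.
#' @export
subband_information_quantity <- function(x, fs, n_bins = 64L) {
  # depth so that the final approximation band is ~0-3 Hz
  levels <- max(2L, min(8L, as.integer(ceiling(log2((fs / 2) / 4)))))
  dec <- dwt_db4(x, levels)
  # detail level j spans fs/2^(j+1) .. fs/2^j
  tops <- fs / 2^seq_len(levels)
  gamma_lv <- which(tops > 32)
  gamma_fallback <- length(gamma_lv) == 0L
  if (gamma_fallback) gamma_lv <- 1L
  # subband histograms share the full signal's support so the entropies are
  # sensitive to how much energy each band actually carries
  rng <- range(x)
  pick <- function(lvls) {
    if (length(lvls) == 0L) return(0)
    rec <- Reduce(`+`, lapply(lvls, function(j) dwt_reconstruct(dec, j)))
    shannon_entropy(rec, n_bins, rng = rng)
  }
  bot <- function(lo, hi) which(tops <= hi & tops > lo)   # detail levels inside (lo, hi]
  out <- c(
    iq_delta = shannon_entropy(dwt_reconstruct(dec, "approx"), n_bins, rng = rng),
    iq_theta = pick(bot(3, 8)[length(bot(3, 8))]),          # band just above approx
    iq_alpha = pick(bot(6, 16)[1]),
    iq_beta  = pick(bot(12, 32)[1]),
    iq_gamma = pick(gamma_lv)
  )
  attr(out, "gamma_fallback") <- gamma_fallback
  out
}

#' Real cepstrum
#'
#' `c = Re(ifft(log(|fft(x)| + eps)))`; the classic quefrency-domain
#' representation used for echo detection and spectral-envelope summaries.
#' @param x numeric samples.
#' @export
real_cepstrum <- function(x) {
  sp <- abs(stats::fft(x))
  Re(stats::fft(log(sp + 1e-12), inverse = TRUE)) / length(x)
}

#' First cepstrum coefficients
#'
#' Returns `c[1]` and `c[2]` of the real cepstrum (`c[0]`, which carries only
#' overall log-amplitude, is excluded), summarizing the rate of change of
#' spectral band power.
#' @param x numeric samples.
#' @export
cepstrum_coefficients <- function(x) {
  cep <- real_cepstrum(x)
  c(cepstrum_1 = cep[2L], cepstrum_2 = cep[3L])
}

#' Hjorth mobility and complexity
#'
#' Variance-ratio descriptors of mean signal frequency and its rate of
#' change: `mobility = sqrt(var(diff(x)) / var(x))`,
#' `complexity = mobility(diff(x)) / mobility(x)`. A constant signal maps to
#' `(0, 0)`.
#' @param x numeric samples.
#' @export
hjorth_params <- function(x) {
  v0 <- stats::var(x)
  if (!is.finite(v0) || v0 <= 0) return(c(hjorth_mobility = 0, hjorth_complexity = 0))
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  cmp <- if (v1 > 0) sqrt(v2 / v1) / mob else 0
  c(hjorth_mobility = mob, hjorth_complexity = cmp)
}

.embed_delay <- function(x) {
  # first zero crossing of the autocorrelation
  ac <- stats::acf(x, lag.max = min(length(x) - 2L, 100L), plot = FALSE)$acf[-1]
  z <- which(ac <= 0)
  if (length(z) == 0L) max(1L, length(ac) %/% 4L) else z[1L]
}

.mean_period <- function(x, fs) {
  sp <- welch_psd(x, fs)
  pw <- sp$psd[-1]; fr <- sp$freq[-1]
  if (sum(pw) <= 0) return(length(x))
  fm <- sum(fr * pw) / sum(pw)
  max(1L, as.integer(round(fs / max(fm, 1e-6))))
}

#' Largest Lyapunov exponent (Rosenstein), Higuchi fractal dimension,
#' and false-nearest-neighbour fraction
#'
#' Three nonlinear-dynamics summaries of a single channel:
#' * `lyapunov`: largest Lyapunov exponent per sample via Rosenstein's
#'   nearest-neighbour divergence method (embedding dimension 5, delay at the
#'   first autocorrelation zero crossing, Theiler window = mean period).
#' * `higuchi_fd`: Higuchi fractal dimension with `k_max = 10` (white noise
#'   approaches 2, smooth curves approach 1).
#' * `fnn`: Kennel false-nearest-neighbour fraction at embedding dimension 3
#'   with tolerance 15.
#'
#' Series too short for the embedding return 0 with a `"too_short"` attribute.
#' @param x numeric samples.
#' @param fs sampling rate, Hz.
#' @export
nonlinear_features <- function(x, fs) {
  out <- c(lyapunov = 0, higuchi_fd = higuchi_fd(x), fnn = 0)
  if (stats::var(x) <= 0) {
    out["higuchi_fd"] <- 1
    return(out)
  }
  tau <- .embed_delay(x)
  out["lyapunov"] <- .lyapunov_rosenstein(x, fs, m = 5L, tau = tau)
  out["fnn"] <- .fnn_fraction(x, dim = 3L, tau = tau, tol = 15)
  out
}

.embed <- function(x, m, tau) {
  n <- length(x) - (m - 1L) * tau
  if (n < 2L) return(NULL)
  sapply(0:(m - 1L), function(k) x[(1:n) + k * tau])
}

.lyapunov_rosenstein <- function(x, fs, m = 5L, tau = 1L, k_steps = 20L) {
  E <- .embed(x, m, tau)
  if (is.null(E) || nrow(E) < 20L) {
    out <- 0; attr(out, "too_short") <- TRUE
    return(out)
  }
  M <- nrow(E)
  theiler <- min(.mean_period(x, fs), M %/% 4L)
  D <- as.matrix(stats::dist(E))
  diag(D) <- Inf
  for (i in seq_len(M)) {
    lo <- max(1L, i - theiler); hi <- min(M, i + theiler)
    D[i, lo:hi] <- Inf
  }
  nn <- max.col(-D, ties.method = "first")
  k_steps <- min(k_steps, M %/% 3L)
  # follow one fixed set of pairs through every step so subset churn cannot
  # masquerade as divergence
  keep <- which(seq_len(M) + k_steps <= M & nn + k_steps <= M &
                  D[cbind(seq_len(M), nn)] > 0 & is.finite(D[cbind(seq_len(M), nn)]))
  if (length(keep) < 5L) return(0)
  logd <- vapply(seq_len(k_steps), function(k) {
    d <- sqrt(rowSums((E[keep + k, , drop = FALSE] - E[nn[keep] + k, , drop = FALSE])^2))
    mean(log(pmax(d, 1e-12)))
  }, 0)
  ok <- which(is.finite(logd))
  if (length(ok) < 3L) return(0)
  stats::coef(stats::lm(logd[ok] ~ ok))[[2L]]
}

#' Higuchi fractal dimension
#' @param x numeric samples.
#' @param k_max largest curve step (default 10).
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  n <- length(x)
  if (stats::var(x) <= 0 || n < k_max + 2L) return(1)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm_ <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) { lm_[m] <- NA; next }
      lm_[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (k * (length(idx) - 1L) * k)
    }
    lk[k] <- mean(lm_, na.rm = TRUE)
  }
  sel <- lk > 0
  if (sum(sel) < 2L) return(1)
  -stats::coef(stats::lm(log(lk[sel]) ~ log(seq_len(k_max)[sel])))[[2L]]
}

.fnn_fraction <- function(x, dim = 3L, tau = 1L, tol = 15) {
  E3 <- .embed(x, dim, tau)
  n4 <- length(x) - dim * tau
  if (is.null(E3) || n4 < 10L) return(0)
  E3 <- E3[seq_len(n4), , drop = FALSE]
  D <- as.matrix(stats::dist(E3))
  diag(D) <- Inf
  nn <- max.col(-D, ties.method = "first")
  r <- D[cbind(seq_len(n4), nn)]
  extra <- abs(x[seq_len(n4) + dim * tau] - x[nn + dim * tau])
  ok <- r > 0
  if (!any(ok)) return(0)
  mean(extra[ok] / r[ok] > tol)
}

#' Autoregressive coefficients at lags 1 and 2
#'
#' Yule-Walker AR(2) fit on the mean-removed signal; the two coefficients
#' summarize short-range temporal structure.
#' @param x numeric samples.
#' @export
arma_coefficients <- function(x) {
  if (stats::var(x) <= 0) return(c(ar_1 = 0, ar_2 = 0))
  fit <- stats::ar.yw(x, aic = FALSE, order.max = 2L, demean = TRUE)
  co <- fit$ar
  c(ar_1 = if (length(co) >= 1L) co[1L] else 0,
    ar_2 = if (length(co) >= 2L) co[2L] else 0)
}

#' Spectral summary features
#'
#' Welch-PSD summaries: median frequency (the frequency splitting total power
#' in half), band powers over delta 0-3 / theta 4-7 / alpha 8-15 / beta 16-31 /
#' gamma 32-Nyquist Hz (trapezoidal integration), the alpha/delta power
#' ratio, the sample standard deviation, and the diffuse-slowing indicator
#' (1 when the PSD peaks below 8 Hz).
#'
#' @param x numeric samples (microvolts).
#' @param fs sampling rate, Hz.
#' @return Named 9-vector.
#' @export
spectral_features <- function(x, fs) {
  sp <- welch_psd(x, fs)
  bands <- qeeg_bands(fs)
  bp <- vapply(bands, function(b) band_power_psd(sp$freq, sp$psd, b[1], b[2]), 0)
  names(bp) <- paste0("bp_", names(bands))
  tot <- trapz(sp$freq, sp$psd)
  med <- if (tot > 0) {
    cum <- cumsum(c(0, (sp$psd[-1] + sp$psd[-length(sp$psd)]) / 2 * diff(sp$freq)))
    i <- which(cum >= tot / 2)[1L]
    if (i == 1L || cum[i] == cum[i - 1L]) sp$freq[i]
    else sp$freq[i - 1L] + (tot / 2 - cum[i - 1L]) / (cum[i] - cum[i - 1L]) *
      (sp$freq[i] - sp$freq[i - 1L])   # linear interpolation of the crossing
  } else 0
  c(median_freq = med, bp,
    std = stats::sd(x),
    alpha_delta_ratio = bp[["bp_alpha"]] / (bp[["bp_delta"]] + 1e-12),
    diffuse_slowing = as.numeric(sp$freq[which.max(sp$psd)] < 8))
}

#' Burst-suppression and low-voltage features
#'
#' Clinical continuity descriptors computed from a 100 ms moving-RMS
#' envelope:
#' * bursts: maximal runs with envelope above `mean + sd` of the envelope
#'   lasting at least 100 ms (count, mean/sd length in seconds, and the five
#'   clinical band powers of the concatenated burst samples);
#' * suppressions: maximal runs with envelope below 10 microvolts lasting at
#'   least 500 ms (count, mean/sd length);
#' * low-voltage fractions: fraction of samples with `|x|` below 5 / 10 / 20
#'   microvolts;
#' * regularity: with `u` the squared amplitudes sorted in decreasing order,
#'   `sqrt(3 * sum(i^2 * u_i) / (N^2 * sum(u_i)))`, clamped to (0, 1]; higher
#'   values mean more stationary, continuous activity. An all-zero signal is
#'   defined to have regularity 1.
#'
#' @param x numeric samples (microvolts).
#' @param fs sampling rate, Hz.
#' @return Named 15-vector.
#' @export
burst_suppression_features <- function(x, fs) {
  n <- length(x)
  env <- moving_rms(x, round(0.1 * fs))
  u <- sort(x^2, decreasing = TRUE)
  reg <- if (sum(u) > 0) min(1, sqrt(3 * sum(seq_len(n)^2 * u) / (n^2 * sum(u)))) else 1

  burst_runs <- runs_true(env > mean(env) + stats::sd(env))
  if (nrow(burst_runs) > 0L) {
    keep <- (burst_runs[, "end"] - burst_runs[, "start"] + 1L) >= round(0.1 * fs)
    burst_runs <- burst_runs[keep, , drop = FALSE]
  }
  blen <- (burst_runs[, "end"] - burst_runs[, "start"] + 1L) / fs
  supp_runs <- runs_true(env < 10)
  if (nrow(supp_runs) > 0L) {
    keep <- (supp_runs[, "end"] - supp_runs[, "start"] + 1L) >= round(0.5 * fs)
    supp_runs <- supp_runs[keep, , drop = FALSE]
  }
  slen <- (supp_runs[, "end"] - supp_runs[, "start"] + 1L) / fs

  if (nrow(burst_runs) > 0L) {
    bs <- unlist(lapply(seq_len(nrow(burst_runs)), function(r)
      x[burst_runs[r, "start"]:burst_runs[r, "end"]]))
    bbp <- spectral_features(bs, fs)[paste0("bp_", names(qeeg_bands(fs)))]
  } else {
    bbp <- stats::setNames(rep(0, 5), paste0("bp_", names(qeeg_bands(fs))))
  }
  names(bbp) <- paste0("burst_", names(bbp))

  c(regularity = reg,
    n_bursts = nrow(burst_runs),
    burst_len_mean = if (length(blen)) mean(blen) else 0,
    burst_len_std = if (length(blen) > 1L) stats::sd(blen) else 0,
    bbp,
    n_suppressions = nrow(supp_runs),
    supp_len_mean = if (length(slen)) mean(slen) else 0,
    supp_len_std = if (length(slen) > 1L) stats::sd(slen) else 0,
    lv_5 = mean(abs(x) < 5), lv_10 = mean(abs(x) < 10), lv_20 = mean(abs(x) < 20))
}

#' Spike and sharp-transient features
#'
#' An excursion is a maximal run with `|x - mean|` beyond 3 standard
#' deviations. Spikes are excursions lasting at most 70 ms; sharp spikes are
#' the subset shorter than 20 ms. `delta_burst_after_spike` is the mean, over
#' spikes, of the delta-band power in the 500 ms after the spike minus the
#' 500 ms before it (windows truncated at the epoch edges; 0 when there are
#' no spikes).
#'
#' @param x numeric samples.
#' @param fs sampling rate, Hz.
#' @export
spike_features <- function(x, fs) {
  mu <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(c(n_spikes = 0, delta_burst_after_spike = 0, n_sharp_spikes = 0))
  runs <- runs_true(abs(x - mu) > 3 * s)
  if (nrow(runs) == 0L)
    return(c(n_spikes = 0, delta_burst_after_spike = 0, n_sharp_spikes = 0))
  dur <- (runs[, "end"] - runs[, "start"] + 1L) / fs
  spikes <- runs[dur <= 0.07, , drop = FALSE]
  n_sharp <- sum(dur < 0.02)
  dbs <- 0
  if (nrow(spikes) > 0L) {
    w <- round(0.5 * fs)
    diffs <- vapply(seq_len(nrow(spikes)), function(r) {
      aft <- x[(spikes[r, "end"] + 1L):min(length(x), spikes[r, "end"] + w)]
      bef <- x[max(1L, spikes[r, "start"] - w):max(1L, spikes[r, "start"] - 1L)]
      dp <- function(seg) {
        if (length(seg) < 16L) return(NA_real_)
        sp <- welch_psd(seg, fs)
        band_power_psd(sp$freq, sp$psd, 0, 3)
      }
      dp(aft) - dp(bef)
    }, 0)
    dbs <- if (all(is.na(diffs))) 0 else mean(diffs, na.rm = TRUE)
  }
  c(n_spikes = nrow(spikes), delta_burst_after_spike = dbs, n_sharp_spikes = n_sharp)
}
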