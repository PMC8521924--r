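# Shared signal-processing primitives: Welch spectra, analytic signal,
# Daubechies-4 wavelet decomposition, envelopes. All operate on plain numeric
# vectors in microvolts; frequencies in Hz.

# Hann-windowed Welch PSD. One-sided density; segments are mean-removed.
# Defaults to 1 s segments with 50% overlap; a single full-length segment is
# used when the series is shorter than one segment.
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(n, as.integer(nperseg %||% round(fs)))
  if (nperseg < 8L) nperseg <- min(n, 8L)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nf)])^2 * scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # fold two-sided power into the one-sided density (not DC / Nyquist)
  inner <- 2:(nf - if (nperseg %% 2L == 0L) 1L else 0L)
  psd[inner] <- 2 * psd[inner]
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd, nperseg = nperseg)
}

# Integrated PSD over [lo, hi] (inclusive bin selection, trapezoid rule).
band_power_psd <- function(freq, psd, lo, hi) {
  sel <- which(freq >= lo & freq <= hi)
  if (length(sel) == 0L) return(0)
  if (length(sel) == 1L) return(psd[sel] * (freq[2] - freq[1]))
  trapz(freq[sel], psd[sel])
}

# Canonical qEEG band edges in Hz (delta 0-3, theta 4-7, alpha 8-15,
# beta 16-31, gamma 32-Nyquist).
qeeg_bands <- function(fs) {
  list(delta = c(0, 3), theta = c(4, 7), alpha = c(8, 15),
       beta = c(16, 31), gamma = c(32, fs / 2))
}

# Analytic-signal instantaneous phase via the frequency-domain Hilbert mask.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

instantaneous_phase <- function(x) Arg(analytic_signal(x - mean(x)))

# --- Daubechies-4 (4-tap) discrete wavelet transform --------------------------
# Hand-rolled pyramid transform with periodic boundary handling; used by the
# subband information quantity features. The signal is reflection-padded to a
# multiple of 2^levels and truncated after reconstruction.

.db4_h <- c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604)
.db4_g <- c(-0.1294095225512604, -0.2241438680420134,
            0.8365163037378079, -0.4829629131445341)

.dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  out <- numeric(half)
  for (k in seq_along(filt)) {
    idx <- ((2L * seq_len(half) - 2L + (k - 1L)) %% n) + 1L
    out <- out + filt[k] * x[idx]
  }
  out
}

.idwt_step <- function(a, d) {
  n <- 2L * length(a)
  up_a <- numeric(n); up_a[seq(1L, n, by = 2L)] <- a
  up_d <- numeric(n); up_d[seq(1L, n, by = 2L)] <- d
  out <- numeric(n)
  for (k in seq_along(.db4_h)) {
    idx <- ((seq_len(n) - 1L - (k - 1L)) %% n) + 1L
    out <- out + .db4_h[k] * up_a[idx] + .db4_g[k] * up_d[idx]
  }
  out
}

# Decompose to `levels`; returns list(approx, details = list(D1..Dlevels), n).
dwt_db4 <- function(x, levels) {
  n <- length(x)
  n2 <- as.integer(ceiling(n / 2^levels) * 2^levels)
  if (n2 > n) {
    pad <- rev(x)[seq_len(n2 - n)]
    x <- c(x, pad)
  }
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    details[[j]] <- .dwt_step(a, .db4_g)
    a <- .dwt_step(a, .db4_h)
  }
  list(approx = a, details = details, n = n, padded = n2)
}

# Reconstruct the time-domain signal carried by one component of the pyramid:
# which = "approx" or detail level j (integer). Other coefficients are zeroed.
dwt_reconstruct <- function(dec, which) {
  levels <- length(dec$details)
  a <- if (identical(which, "approx")) dec$approx else numeric(length(dec$approx))
  for (j in rev(seq_len(levels))) {
    d <- if (is.numeric(which) && which == j) dec$details[[j]] else numeric(length(dec$details[[j]]))
    a <- .idwt_step(a, d)
  }
  a[seq_len(dec$n)]
}

# Moving RMS envelope, centred window of `win` samples; edges use the nearest
# full window value so the envelope has the same length as the input.
moving_rms <- function(x, win) {
  win <- max(1L, as.integer(win))
  n <- length(x)
  if (win >= n) return(rep(sqrt(mean(x^2)), n))
  cs <- c(0, cumsum(x^2))
  m <- (cs[(win + 1L):(n + 1L)] - cs[1L:(n - win + 1L)]) / win   # length n-win+1
  lead <- (win - 1L) %/% 2L
  env <- c(rep(m[1L], lead), m, rep(m[length(m)], n - length(m) - lead))
  sqrt(env)
}

# Circular normalized cross-correlation between two vectors of equal length.
# Returns list(lags, r) with lags in samples, in (-n/2, n/2]; r in [-1, 1].
circular_xcorr <- function(x, y) {
  n <- length(x)
  x <- x - mean(x); y <- y - mean(y)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0) return(list(lags = 0L, r = 0))
  cc <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(y)), inverse = TRUE)) / n
  r <- cc / (sx * sy)
  half <- n %/% 2L
  lags <- c(0:half, -((n - half - 1L):1L))
  ord <- order(lags)
  list(lags = lags[ord], r = r[ord])
}
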