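# Channel-pair connectivity features. All six are computed on every unordered
# channel pair (ordered pairs for Granger causality) and averaged, yielding
# one value per epoch per feature.

# Windowed segment FFTs shared by coherence computations: returns
# [n_freq x n_seg] complex matrix.
.seg_ffts <- function(x, nperseg, step) {
  n <- length(x)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  nf <- nperseg %/% 2L + 1L
  out <- matrix(0+0i, nf, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nperseg - 1L)]
    out[, k] <- stats::fft((seg - mean(seg)) * w)[seq_len(nf)]
  }
  out
}

# Histogram mutual information in bits (n_bins x n_bins equal-width grid).
.mutual_info <- function(x, y, n_bins = 16L) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  bx <- findInterval(x, seq(min(x), max(x), length.out = n_bins + 1L),
                     rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(y, seq(min(y), max(y), length.out = n_bins + 1L),
                     rightmost.closed = TRUE, all.inside = TRUE)
  j <- table(bx, by) / length(x)
  px <- rowSums(j); py <- colSums(j)
  nz <- j > 0
  sum(j[nz] * log2(j[nz] / outer(px, py)[nz]))
}

# Bivariate Granger F statistic x -> y at lag order p (OLS, fast lm-free fit).
.granger_f <- function(lag_x, lag_y, y_fut, p) {
  n <- length(y_fut)
  Xr <- cbind(1, lag_y[, seq_len(p), drop = FALSE])
  Xf <- cbind(Xr, lag_x[, seq_len(p), drop = FALSE])
  rss <- function(X) {
    f <- stats::.lm.fit(X, y_fut)
    sum(f$residuals^2)
  }
  rss_r <- rss(Xr); rss_f <- rss(Xf)
  df2 <- n - ncol(Xf)
  if (df2 <= 0 || rss_f <= 0) return(0)
  max(0, (rss_r - rss_f) / p / (rss_f / df2))
}

#' Bivariate Granger causality F statistic
#'
#' Tests whether past values of `x` improve the prediction of `y` beyond
#' `y`'s own past, via OLS fits of order `p` (chosen by AIC on `y` when
#' omitted, capped at `max_order`). Larger F = stronger evidence that `x`
#' Granger-causes `y`.
#'
#' @param x,y numeric series of equal length.
#' @param p lag order; default picks it by AIC on `y`.
#' @param max_order cap for the AIC order search.
#' @export
granger_causality <- function(x, y, p = NULL, max_order = 10L) {
  ns <- length(y)
  if (is.null(p)) {
    p <- if (stats::var(y) == 0) 1L
         else max(1L, stats::ar.yw(y, order.max = max_order, demean = TRUE)$order)
  }
  mk <- function(v) sapply(seq_len(p), function(k) v[(p + 1L - k):(ns - k)])
  .granger_f(mk(x), mk(y), y[(p + 1L):ns], p)
}

#' Connectivity features of a multichannel epoch
#'
#' Six pairwise-interaction summaries, averaged over channel pairs:
#'
#' * `coherence_delta`: mean magnitude-squared coherence over 0-4 Hz
#'   (Welch cross-spectra, Hann windows).
#' * `mutual_info`: histogram mutual information, 16 x 16 bins, in bits.
#' * `granger_all`: mean bivariate Granger-causality F statistic over ordered
#'   pairs; the lag order is picked per target channel by AIC (max 10).
#' * `pli`: phase lag index, `|mean(sign(dphi))|` with `dphi` the wrapped
#'   analytic-signal phase difference (0 for identical or anti-phase signals,
#'   1 for a constant non-zero phase lead).
#' * `xcorr_mag`: maximum absolute normalized (circular) cross-correlation.
#' * `xcorr_lag`: mean absolute lag, in milliseconds, of the correlation peak.
#'
#' @param ep channels-by-samples matrix (>= 2 channels).
#' @param fs sampling rate, Hz.
#' @param max_order maximum Granger lag order (default 10).
#' @return Named 6-vector.
#' @export
connectivity_features <- function(ep, fs, max_order = 10L) {
  nc <- nrow(ep); ns <- ncol(ep)
  if (nc < 2L) stop_param("connectivity features need at least 2 channels")
  pairs <- utils::combn(nc, 2L)

  nperseg <- min(ns, 64L)
  step <- max(1L, nperseg %/% 2L)
  ffts <- lapply(seq_len(nc), function(c) .seg_ffts(ep[c, ], nperseg, step))
  freqs <- (seq_len(nperseg %/% 2L + 1L) - 1L) * fs / nperseg
  dsel <- which(freqs <= 4)
  phases <- lapply(seq_len(nc), function(c) instantaneous_phase(ep[c, ]))

  # per-channel AR order by AIC (used as the Granger lag order of the target)
  ords <- vapply(seq_len(nc), function(c) {
    if (stats::var(ep[c, ]) == 0) return(1L)
    max(1L, stats::ar.yw(ep[c, ], order.max = max_order, demean = TRUE)$order)
  }, 0L)
  lags <- lapply(seq_len(nc), function(c) {
    x <- ep[c, ]
    sapply(seq_len(max_order), function(k) x[(max_order + 1L - k):(ns - k)])
  })
  futs <- lapply(seq_len(nc), function(c) ep[c, (max_order + 1L):ns])

  coh <- mi <- pli <- xm <- xl <- numeric(ncol(pairs))
  gf <- numeric(0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    fi <- ffts[[i]]; fj <- ffts[[j]]
    pxx <- rowMeans(abs(fi)^2); pyy <- rowMeans(abs(fj)^2)
    pxy <- rowMeans(fi * Conj(fj))
    denom <- pxx * pyy
    msc <- ifelse(denom > 0, abs(pxy)^2 / denom, 0)
    coh[k] <- mean(msc[dsel])
    mi[k] <- .mutual_info(ep[i, ], ep[j, ])
    dphi <- phases[[i]] - phases[[j]]
    dphi <- atan2(sin(dphi), cos(dphi))     # wrap to (-pi, pi]
    pli[k] <- abs(mean(sign(dphi)))
    cc <- circular_xcorr(ep[i, ], ep[j, ])
    best <- which.max(abs(cc$r) - abs(cc$lags) * 1e-12)  # ties -> smallest |lag|
    xm[k] <- abs(cc$r[best])
    xl[k] <- abs(cc$lags[best]) * 1000 / fs
    p_ij <- ords[j]; p_ji <- ords[i]
    gf <- c(gf,
            .granger_f(lags[[i]], lags[[j]], futs[[j]], p_ij),
            .granger_f(lags[[j]], lags[[i]], futs[[i]], p_ji))
  }
  c(coherence_delta = mean(coh), mutual_info = mean(mi),
    granger_all = mean(gf), pli = mean(pli),
    xcorr_mag = mean(xm), xcorr_lag = mean(xl))
}
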