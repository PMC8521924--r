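#' Canonical feature registry
#'
#' The 58 quantitative-EEG features the pipeline extracts, in canonical column
#' order, with their family: 25 complexity, 27 continuity, 6 connectivity.
#'
#' @return A tibble with columns `name` and `family`.
#' @export
qeeg_feature_names <- function() {
  complexity <- c("shannon",
                  paste0("tsallis_q", tsallis_q_default),
                  paste0("iq_", c("delta", "theta", "alpha", "beta", "gamma")),
                  "cepstrum_1", "cepstrum_2",
                  "lyapunov", "higuchi_fd", "hjorth_mobility", "hjorth_complexity",
                  "fnn", "ar_1", "ar_2")
  continuity <- c("median_freq",
                  paste0("bp_", c("delta", "theta", "alpha", "beta", "gamma")),
                  "std", "alpha_delta_ratio", "regularity",
                  "lv_5", "lv_10", "lv_20", "diffuse_slowing",
                  "n_spikes", "delta_burst_after_spike", "n_sharp_spikes",
                  "n_bursts", "burst_len_mean", "burst_len_std",
                  paste0("burst_bp_", c("delta", "theta", "alpha", "beta", "gamma")),
                  "n_suppressions", "supp_len_mean", "supp_len_std")
  connectivity <- c("coherence_delta", "mutual_info", "granger_all",
                    "pli", "xcorr_mag", "xcorr_lag")
  tibble::tibble(
    name = c(complexity, continuity, connectivity),
    family = rep(c("complexity", "continuity", "connectivity"),
                 c(length(complexity), length(continuity), length(connectivity)))
  )
}

# All univariate features of one channel, in registry order (52 values).
.channel_features <- function(x, fs, n_bins = 64L, tsallis_q = tsallis_q_default) {
  hj <- hjorth_params(x)
  nl <- nonlinear_features(x, fs)
  ar <- arma_coefficients(x)
  sp <- spectral_features(x, fs)
  bs <- burst_suppression_features(x, fs)
  spk <- spike_features(x, fs)
  c(shannon = shannon_entropy(x, n_bins),
    tsallis_entropies(x, tsallis_q, n_bins),
    subband_information_quantity(x, fs, n_bins),
    cepstrum_coefficients(x),
    nl["lyapunov"], nl["higuchi_fd"], hj, nl["fnn"], ar,
    sp["median_freq"],
    sp[paste0("bp_", c("delta", "theta", "alpha", "beta", "gamma"))],
    sp["std"], sp["alpha_delta_ratio"],
    bs["regularity"], bs[c("lv_5", "lv_10", "lv_20")],
    sp["diffuse_slowing"],
    spk,
    bs[c("n_bursts", "burst_len_mean", "burst_len_std")],
    stats::setNames(bs[paste0("burst_bp_", c("delta", "theta", "alpha", "beta", "gamma"))],
                    paste0("burst_bp_", c("delta", "theta", "alpha", "beta", "gamma"))),
    bs[c("n_suppressions", "supp_len_mean", "supp_len_std")])
}

.epoch_features <- function(ep, fs, n_bins, tsallis_q, permissive) {
  uni <- vapply(seq_len(nrow(ep)),
                function(c) unname(.channel_features(ep[c, ], fs, n_bins, tsallis_q)),
                numeric(52L))
  uni <- rowMeans(uni)
  conn <- if (nrow(ep) >= 2L) {
    unname(connectivity_features(ep, fs))
  } else if (permissive) {
    rep(0, 6L)
  } else {
    stop_param("connectivity features need >= 2 channels (set permissive = TRUE to emit zeros)")
  }
  c(uni, conn)
}

#' Extract the 58-feature matrix from an epoch set
#'
#' Computes every registry feature for every epoch: univariate features are
#' computed per channel and averaged across channels; connectivity features
#' are averaged across channel pairs. The computation is deterministic and
#' embarrassingly parallel across epochs.
#'
#' @param es an [epoch_set()].
#' @param n_bins amplitude-histogram bins for the entropy features.
#' @param tsallis_q Tsallis order grid.
#' @param workers number of parallel workers (forked; results are
#'   bit-identical across worker counts).
#' @param permissive if `TRUE`, single-channel epochs yield zero connectivity
#'   features instead of an error.
#' @return A tibble of class `qeeg_features`: `epoch_index` plus 58 named
#'   feature columns; attributes record the sampling rate and extraction
#'   settings.
#' @export
extract_features <- function(es, n_bins = 64L, tsallis_q = tsallis_q_default,
                             workers = 1L, permissive = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  ne <- n_epochs(es)
  one <- function(i) .epoch_features(epoch_data(es, i), es$fs, n_bins, tsallis_q, permissive)
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(ne), one, mc.cores = workers)
  } else {
    lapply(seq_len(ne), one)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- qeeg_feature_names()$name
  out <- tibble::as_tibble(m)
  out <- dplyr::mutate(out, epoch_index = seq_len(ne), .before = 1L)
  class(out) <- c("qeeg_features", class(out))
  attr(out, "fs") <- es$fs
  attr(out, "standardized") <- FALSE
  attr(out, "subject_ids") <- es$subject_ids
  out
}

#' Extract the numeric feature matrix from a `qeeg_features` tibble
#' @param fm a `qeeg_features` tibble.
#' @export
feature_matrix <- function(fm) {
  as.matrix(fm[, setdiff(names(fm), "epoch_index"), drop = FALSE])
}

#' Standardize (z-score) a feature matrix
#'
#' Per-column centring and scaling; constant columns map to zero. The means
#' and standard deviations are stored so [destandardize_features()] is an
#' exact inverse.
#'
#' @param fm a `qeeg_features` tibble.
#' @export
standardize_features <- function(fm) {
  m <- feature_matrix(fm)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  # columns whose variation is below numerical precision are treated as
  # constant, otherwise the z-scores amplify pure rounding noise
  const <- sdv == 0 | sdv < 1e-8 * abs(mu)
  scl <- ifelse(const, 1, sdv)
  z <- sweep(sweep(m, 2L, mu), 2L, scl, "/")
  z[, const] <- 0
  out <- fm
  out[, colnames(m)] <- tibble::as_tibble(z)
  attr(out, "standardized") <- TRUE
  attr(out, "center") <- mu
  attr(out, "scale") <- scl
  out
}

#' @rdname standardize_features
#' @export
destandardize_features <- function(fm) {
  if (!isTRUE(attr(fm, "standardized"))) return(fm)
  m <- feature_matrix(fm)
  raw <- sweep(sweep(m, 2L, attr(fm, "scale"), "*"), 2L, attr(fm, "center"), "+")
  out <- fm
  out[, colnames(m)] <- tibble::as_tibble(raw)
  attr(out, "standardized") <- FALSE
  out
}

#' Write / read a feature matrix as CSV
#'
#' Plain CSV with the canonical feature names as header and one row per
#' epoch (first column `epoch_index`).
#' @param fm a `qeeg_features` tibble.
#' @param path file path.
#' @export
write_features_csv <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @param fs sampling rate to record on the loaded object.
#' @export
read_features_csv <- function(path, fs = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(qeeg_feature_names()$name, names(df))
  if (length(miss) > 0L)
    stop_format(sprintf("feature CSV is missing columns: %s", paste(miss, collapse = ", ")))
  out <- tibble::as_tibble(df)
  class(out) <- c("qeeg_features", class(out))
  attr(out, "fs") <- fs
  attr(out, "standardized") <- FALSE
  out
}
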