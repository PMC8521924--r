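# Shared fixture builders. Everything is generated in code at test time;
# heavyweight simulation products used by several acceptance blocks are
# memoized for the duration of the test run.

# A multichannel epoch set of pure sinusoids (deterministic given seed).
sine_epoch_set <- function(n_epochs = 4, n_channels = 2, fs = 200, n_samples = 200,
                           freq = 10, amp = 20, phase_jitter = 0, seed = 1) {
  t <- (seq_len(n_samples) - 1) / fs
  arr <- array(0, c(n_epochs, n_channels, n_samples))
  set.seed(seed)
  for (i in seq_len(n_epochs)) {
    ph <- runif(1, 0, 2 * pi)
    for (c in seq_len(n_channels)) {
      arr[i, c, ] <- amp * sin(2 * pi * freq * t + ph + phase_jitter * (c - 1))
    }
  }
  epoch_set(arr, fs)
}

# A small continuous recording with labelled events, for EDF round trips.
demo_recording <- function(n_channels = 2, fs = 100, secs = 10, seed = 3) {
  set.seed(seed)
  n <- fs * secs
  sig <- matrix(0, n_channels, n)
  for (c in seq_len(n_channels)) {
    sig[c, ] <- 30 * sin(2 * pi * (4 + c) * (0:(n - 1)) / fs) + rnorm(n, 0, 5)
  }
  structure(list(signals = sig, fs = fs,
                 channel_names = paste0("EEG", seq_len(n_channels)),
                 events = tibble::tibble(sample = as.integer(c(150, 450, 750)),
                                         label = c("stim", "stim", "stim"))),
            class = "eeg_recording")
}

.acc_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- force(expr)
  .acc_cache[[key]]
}

# The headline detection benchmark: generator defaults for prevalence,
# magnitude, class structure and subject heterogeneity; 1000 epochs with 8
# channels (desk-scale channel count; see the methods vignette).
acceptance_benchmark <- function() {
  memo("bench", {
    cfg <- synth_config(n_epochs = 1000, n_channels = 8, magnitude = c(5, 10),
                        seed = 1)
    ds <- make_dataset(cfg)
    fm <- standardize_features(extract_features(ds$epochs))
    list(ds = ds, fm = fm)
  })
}

# The correction-stage benchmark: 600 four-channel epochs, single subject.
correction_benchmark <- function() {
  memo("corr", {
    cfg <- synth_config(n_epochs = 600, n_channels = 4, magnitude = c(5, 10),
                        n_subjects = 1, subject_heterogeneity = 0, seed = 5)
    ds <- make_dataset(cfg)
    fm <- standardize_features(extract_features(ds$epochs))
    det <- run_detection(ds$epochs, fm, "hbos", 0.172, seed = 1)
    clean <- subset_epochs(ds$epochs, which(!det$flag))
    pairs <- build_training_pairs(clean, h = 32, G = 40, pairs_per_epoch = 2, seed = 11)
    ens <- train_interpolator(pairs, seed = 11)
    list(cfg = cfg, ds = ds, fm = fm, det = det, ens = ens)
  })
}
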