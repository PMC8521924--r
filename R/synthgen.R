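#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the statistical structure the detection pipeline
#' assumes: thousands of short multichannel trials whose clean signal is a sum
#' of band-limited oscillators plus 1/f^alpha background noise, a weak
#' class-dependent alpha-band power modulation so a downstream classifier has
#' recoverable signal, and rare, time-localized, additive artifacts (blink,
#' muscle burst, electrode pop, slow drift) with exact ground-truth masks.
#'
#' Defaults mirror the acquisition this pipeline targets: 32 channels at
#' 200 Hz, 1 s epochs, 6 condition classes, 7 subjects, and an artifact
#' prevalence of 0.172.
#'
#' @param n_epochs number of epochs to simulate.
#' @param n_channels channels per epoch (>= 2).
#' @param fs sampling rate, Hz.
#' @param epoch_len epoch duration, seconds.
#' @param n_classes number of condition classes (labels `0 .. n_classes-1`).
#' @param artifact_prevalence fraction of epochs carrying an artifact; must be
#'   below 0.5 (artifacts have to be outliers for unsupervised detection).
#' @param artifact_mix named weights over `blink`, `muscle`, `pop`, `drift`;
#'   must sum to 1.
#' @param class_effect relative alpha-band amplitude modulation per class:
#'   class `k` scales alpha amplitude by `1 + class_effect * k`.
#' @param noise_exponent spectral slope `alpha` of the 1/f^alpha background.
#' @param magnitude artifact peak amplitude in units of the clean epoch's
#'   standard deviation; a length-2 vector is a uniform range.
#' @param n_subjects epochs are split into this many contiguous subject blocks.
#' @param subject_heterogeneity log-normal sd of per-subject gain and of
#'   per-subject artifact-mix tilt (0 disables subject idiosyncrasies).
#' @param osc_scale global multiplier on the oscillator amplitudes (0 leaves
#'   pure 1/f noise; used to validate the noise spectrum).
#' @param seed integer; one global seed drives every draw through
#'   counter-based substreams, so per-epoch generation is order-independent.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_epochs = 1400, n_channels = 32, fs = 200,
                         epoch_len = 1, n_classes = 6,
                         artifact_prevalence = 0.172,
                         artifact_mix = c(blink = 0.4, muscle = 0.3,
                                          pop = 0.2, drift = 0.1),
                         class_effect = 0.2, noise_exponent = 1,
                         magnitude = c(5, 10), n_subjects = 7,
                         subject_heterogeneity = 0.15, osc_scale = 1,
                         seed = 0) {
  if (artifact_prevalence < 0 || artifact_prevalence >= 0.5)
    stop_param("artifact_prevalence must be in [0, 0.5): artifacts must be infrequent outliers")
  if (!setequal(names(artifact_mix), c("blink", "muscle", "pop", "drift")))
    stop_param("artifact_mix must name blink, muscle, pop, drift")
  if (abs(sum(artifact_mix) - 1) > 1e-8) stop_param("artifact_mix weights must sum to 1")
  if (n_channels < 2) stop_param("need at least 2 channels")
  structure(list(n_epochs = as.integer(n_epochs), n_channels = as.integer(n_channels),
                 fs = fs, epoch_len = epoch_len, n_classes = as.integer(n_classes),
                 artifact_prevalence = artifact_prevalence,
                 artifact_mix = artifact_mix[c("blink", "muscle", "pop", "drift")],
                 class_effect = class_effect, noise_exponent = noise_exponent,
                 magnitude = magnitude, n_subjects = as.integer(n_subjects),
                 subject_heterogeneity = subject_heterogeneity,
                 osc_scale = osc_scale, seed = as.integer(seed)),
            class = "synth_config")
}

# Band oscillator prototypes: frequency range (Hz) and baseline amplitude (uV).
.synth_bands <- list(
  delta = list(f = c(1, 3), amp = 6),
  theta = list(f = c(4, 7), amp = 3),
  alpha = list(f = c(8, 13), amp = 4),
  beta  = list(f = c(16, 30), amp = 1.5),
  gamma = list(f = c(33, 45), amp = 0.8)
)

# 1/f^alpha noise via spectral shaping of white noise; unit sd.
.pink_noise <- function(n, alpha) {
  nf <- n %/% 2L
  amp <- (seq_len(nf))^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = c(0, amp, rep(0, n - nf - 1L)),
                  argument = c(0, ph, rep(0, n - nf - 1L)))
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

#' Simulate one artifact-free epoch
#'
#' Sum of delta/theta/alpha/beta/gamma oscillators (per-epoch frequencies,
#' per-channel amplitudes and phases) plus 1/f^alpha background noise, in
#' microvolts. `class_id` scales the alpha-band amplitude by
#' `1 + class_effect * class_id`.
#'
#' @param cfg a [synth_config()].
#' @param class_id condition class in `0 .. n_classes-1`.
#' @param seed integer seed; the same seed reproduces the epoch exactly.
#' @return A channels-by-samples matrix.
#' @export
make_clean_epoch <- function(cfg, class_id = 0L, seed = 0) {
  if (class_id < 0 || class_id >= cfg$n_classes) stop_param("class_id out of range")
  ns <- as.integer(round(cfg$fs * cfg$epoch_len))
  nc <- cfg$n_channels
  with_seed(seed, {
    t <- (seq_len(ns) - 1) / cfg$fs
    x <- matrix(0, nc, ns)
    for (b in names(.synth_bands)) {
      bb <- .synth_bands[[b]]
      f <- stats::runif(1, bb$f[1], bb$f[2])
      amp <- bb$amp * stats::runif(nc, 0.7, 1.3) * cfg$osc_scale
      if (b == "alpha") amp <- amp * (1 + cfg$class_effect * class_id)
      ph <- stats::runif(1, 0, 2 * pi) + stats::rnorm(nc, 0, 0.4)
      x <- x + amp * sin(outer(2 * pi * f * t, ph, `+`) |> t())
    }
    noise <- matrix(0, nc, ns)
    for (c in seq_len(nc)) noise[c, ] <- .pink_noise(ns, cfg$noise_exponent)
    x + 4 * noise
  })
}

#' Inject a ground-truth artifact into an epoch
#'
#' Additive, time-localized artifact templates following the classic EEG
#' artifact taxonomy: `blink` (slow biphasic pulse, 300-500 ms, largest on the
#' first ~4 channels), `muscle` (20-80 Hz noise burst, 200-600 ms, on a random
#' subset of channels), `pop` (step plus exponential decay on exactly one
#' channel), `drift` (sub-1 Hz ramp across the whole epoch). `magnitude`
#' scales the template's peak amplitude relative to the clean epoch's standard
#' deviation; magnitude 0 returns the epoch unchanged (mask still reported).
#'
#' @param ep channels-by-samples matrix (microvolts).
#' @param kind one of `"blink"`, `"muscle"`, `"pop"`, `"drift"`.
#' @param magnitude peak amplitude in clean-signal standard deviations.
#' @param fs sampling rate, Hz.
#' @param seed integer seed for the template draws.
#' @param channel_order optional channel permutation applied to the spatial
#'   pattern (used to emulate subject-specific montage idiosyncrasies).
#' @return A list with `data` (the contaminated matrix) and `mask`, a one-row
#'   tibble `(kind, channel, start, end)` with a 0-based half-open sample
#'   interval; `channel` is `NA` for multi-channel artifacts.
#' @export
inject_artifact <- function(ep, kind, magnitude, fs, seed = 0,
                            channel_order = NULL) {
  if (!kind %in% c("blink", "muscle", "pop", "drift"))
    stop_param(sprintf("unknown artifact kind '%s'", kind))
  nc <- nrow(ep); ns <- ncol(ep)
  ord <- channel_order %||% seq_len(nc)
  sd0 <- stats::sd(as.vector(ep))
  peak <- magnitude * sd0
  with_seed(seed, {
    out <- ep
    if (kind == "blink") {
      L <- min(ns, as.integer(round(stats::runif(1, 0.3, 0.5) * fs)))
      s <- sample.int(ns - L + 1L, 1L) - 1L          # 0-based start
      u <- seq(-1, 1, length.out = L)
      w <- u * exp(-4 * u^2); w <- w / max(abs(w))
      cw <- exp(-(seq_len(nc) - 1) / 3)[order(ord)]  # largest on ord[1..4]
      out[, (s + 1L):(s + L)] <- out[, (s + 1L):(s + L)] + peak * outer(cw, w)
      mask_ch <- NA_integer_; int <- c(s, s + L)
    } else if (kind == "muscle") {
      L <- min(ns, as.integer(round(stats::runif(1, 0.2, 0.6) * fs)))
      s <- sample.int(ns - L + 1L, 1L) - 1L
      hi <- min(80, 0.45 * fs)
      bf <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
      env <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
      chans <- sort(sample.int(nc, max(2L, round(stats::runif(1, 0.3, 0.7) * nc))))
      for (c in chans) {
        nz <- signal::filtfilt(bf, stats::rnorm(L + 2 * fs))[(fs + 1):(fs + L)]
        nz <- nz / max(stats::sd(nz), 1e-12)
        out[c, (s + 1L):(s + L)] <- out[c, (s + 1L):(s + L)] +
          0.7 * peak * stats::runif(1, 0.5, 1) * env * nz
      }
      mask_ch <- NA_integer_; int <- c(s, s + L)
    } else if (kind == "pop") {
      ch <- ord[sample.int(nc, 1L)]
      s <- sample.int(max(1L, as.integer(0.6 * ns)), 1L) - 1L
      tau <- stats::runif(1, 0.1, 0.3) * fs
      # abrupt step decaying toward a sustained impedance offset
      w <- 0.2 + 0.8 * exp(-(0:(ns - s - 1L)) / tau)
      out[ch, (s + 1L):ns] <- out[ch, (s + 1L):ns] + sign(stats::runif(1) - 0.5) * peak * w
      mask_ch <- as.integer(ch); int <- c(s, ns)
    } else { # drift
      w <- seq(0, 1, length.out = ns)
      cw <- stats::runif(nc, 0.6, 1) * sign(stats::runif(nc) - 0.5)
      out <- out + 0.8 * peak * outer(cw, w)
      mask_ch <- NA_integer_; int <- c(0L, ns)
    }
    list(data = out,
         mask = tibble::tibble(kind = kind, channel = mask_ch,
                               start = as.integer(int[1]), end = as.integer(int[2])))
  })
}

#' Simulate a labelled epoch set with ground-truth artifacts
#'
#' Generates `cfg$n_epochs` epochs with balanced class labels, splits them into
#' contiguous subject blocks, and injects artifacts into exactly
#' `round(prevalence * n_epochs)` epochs, with kinds sampled from
#' `cfg$artifact_mix`. When `subject_heterogeneity > 0` each subject receives
#' a log-normal amplitude gain, a tilted artifact mix, and a permuted artifact
#' channel pattern, emulating per-setup idiosyncrasies. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return A list: `epochs` (an [epoch_set()] whose `artifact_flags` carry the
#'   ground truth), `truth` (logical vector), and `masks` (tibble with
#'   `epoch_index` (1-based), `kind`, `channel`, 0-based half-open
#'   `start`/`end`, `magnitude`).
#' @export
make_dataset <- function(cfg) {
  n <- cfg$n_epochs
  ns <- as.integer(round(cfg$fs * cfg$epoch_len))
  nc <- cfg$n_channels
  n_art <- as.integer(round(cfg$artifact_prevalence * n))

  labels <- with_seed(sub_seed(cfg$seed, 101), sample(rep_len(0:(cfg$n_classes - 1L), n)))
  art_idx <- with_seed(sub_seed(cfg$seed, 102), sort(sample.int(n, n_art)))
  subj_of <- rep(seq_len(cfg$n_subjects), each = ceiling(n / cfg$n_subjects))[seq_len(n)]

  het <- cfg$subject_heterogeneity
  subj <- lapply(seq_len(cfg$n_subjects), function(s) {
    with_seed(sub_seed(cfg$seed, 103, s), {
      list(gain = if (het > 0) exp(stats::rnorm(1, 0, het)) else 1,
           mix = {
             m <- cfg$artifact_mix * if (het > 0) exp(stats::rnorm(4, 0, 2 * het)) else 1
             m / sum(m)
           },
           order = if (het > 0) sample.int(nc) else seq_len(nc))
    })
  })

  truth <- logical(n)
  truth[art_idx] <- TRUE
  kinds <- character(n)
  mags <- numeric(n)
  for (i in art_idx) {
    s <- subj_of[i]
    kinds[i] <- with_seed(sub_seed(cfg$seed, 104, i),
                          sample(names(subj[[s]]$mix), 1L, prob = subj[[s]]$mix))
    mags[i] <- with_seed(sub_seed(cfg$seed, 105, i),
                         stats::runif(1, min(cfg$magnitude), max(cfg$magnitude)))
  }

  arr <- array(0, c(n, nc, ns))
  mask_rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subj_of[i]
    ep <- make_clean_epoch(cfg, labels[i], seed = sub_seed(cfg$seed, 1, i)) * subj[[s]]$gain
    if (truth[i]) {
      inj <- inject_artifact(ep, kinds[i], mags[i], cfg$fs,
                             seed = sub_seed(cfg$seed, 2, i),
                             channel_order = subj[[s]]$order)
      ep <- inj$data
      mask_rows[[i]] <- dplyr::mutate(inj$mask, epoch_index = i, magnitude = mags[i],
                                      .before = 1L)
    }
    arr[i, , ] <- ep
  }

  es <- epoch_set(arr, cfg$fs, paste0("ch", seq_len(nc)), labels, truth,
                  paste0("s", subj_of),
                  metadata = list(generator = unclass(cfg)))
  list(epochs = es, truth = truth,
       masks = dplyr::bind_rows(mask_rows))
}
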