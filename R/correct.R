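# Self-supervised gap interpolation: learn to predict a removed G-sample
# segment of a clean epoch from the h samples on each side, one small
# encoder-decoder network per missing-sample offset, then splice predictions
# into the most deviant segment of each flagged epoch.

#' Build self-supervised training pairs from clean epochs
#'
#' From each clean epoch, samples `pairs_per_epoch` windows of `2h + G`
#' consecutive samples: the first and last `h` samples are stacked into the
#' context, the middle `G` samples are the prediction target. Epochs shorter
#' than `2h + G` are skipped and counted in the `"skipped"` attribute.
#'
#' @param clean an [epoch_set()] of artifact-free epochs.
#' @param h context half-width in samples (default 32).
#' @param G gap length in samples (default 40, i.e. 200 ms at 200 Hz).
#' @param pairs_per_epoch windows drawn per epoch.
#' @param seed integer seed; window positions are reproducible.
#' @return A list with arrays `context` `[n_pairs, channels, 2h]` and
#'   `target` `[n_pairs, channels, G]`, plus `epoch` (source epoch index),
#'   `h`, `G`, `fs`, `n_channels`.
#' @export
build_training_pairs <- function(clean, h = 32L, G = 40L, pairs_per_epoch = 1L,
                                 seed = 0L) {
  stopifnot(inherits(clean, "epoch_set"))
  ns <- n_samples(clean); nc <- n_channels(clean)
  win <- 2L * h + G
  usable <- ns >= win
  skipped <- if (usable) 0L else n_epochs(clean)
  if (!usable) stop_param(sprintf("epochs are too short (%d) for a %d-sample window", ns, win))
  np <- n_epochs(clean) * pairs_per_epoch
  ctx <- array(0, c(np, nc, 2L * h))
  tgt <- array(0, c(np, nc, G))
  src <- integer(np)
  k <- 0L
  for (i in seq_len(n_epochs(clean))) {
    starts <- with_seed(sub_seed(seed, i),
                        sample.int(ns - win + 1L, pairs_per_epoch, replace = pairs_per_epoch > ns - win + 1L))
    ep <- epoch_data(clean, i)
    for (s in starts) {
      k <- k + 1L
      ctx[k, , seq_len(h)] <- ep[, s:(s + h - 1L)]
      ctx[k, , h + seq_len(h)] <- ep[, (s + h + G):(s + win - 1L)]
      tgt[k, , ] <- ep[, (s + h):(s + h + G - 1L)]
      src[k] <- i
    }
  }
  structure(list(context = ctx, target = tgt, epoch = src,
                 h = h, G = G, fs = clean$fs, n_channels = nc),
            skipped = skipped)
}

.flatten_ctx <- function(ctx) {
  # [n, channels, 2h] -> [n, channels*2h], channel-major within each time step
  n <- dim(ctx)[1L]
  matrix(ctx, nrow = n)
}

#' Train the per-offset gap-interpolation ensemble
#'
#' Trains `G` independent dense encoder-decoder networks; network `q` learns
#' to predict the channel vector at gap offset `q` (0-based) from the same
#' flattened `2h`-sample context. Networks are independent, so the ensemble
#' is trivially parallelizable; training is full-batch, seeded, and
#' deterministic. A non-finite loss aborts with the offending offset.
#'
#' @param pairs training pairs from [build_training_pairs()].
#' @param hidden_sizes encoder/decoder layer widths (default
#'   `c(32, 16, 8, 16, 32)`: three shrinking and three expanding blocks).
#' @param epochs training iterations per network.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @param l2 L2 weight-decay strength (guards against memorizing the clean
#'   training windows).
#' @param workers parallel workers for training the offsets.
#' @return An object of class `interpolator_ensemble`.
#' @export
train_interpolator <- function(pairs, hidden_sizes = c(32L, 16L, 8L, 16L, 32L),
                               epochs = 200L, lr = 5e-3, seed = 0L, l2 = 1e-2,
                               workers = 1L) {
  G <- pairs$G
  X <- .flatten_ctx(pairs$context)
  scale <- sqrt(mean(X^2))               # RMS: robust for non-zero-mean signals
  if (!is.finite(scale) || scale == 0) scale <- 1
  X <- X / scale
  train_one <- function(q) {
    Y <- matrix(pairs$target[, , q, drop = FALSE], nrow = dim(pairs$target)[1L]) / scale
    tryCatch(
      nn_train(X, Y, hidden_sizes, epochs = epochs, lr = lr, seed = sub_seed(seed, q), l2 = l2),
      eegsweep_training_error = function(e) {
        rlang::abort(sprintf("interpolator for offset %d failed: %s", q - 1L,
                             conditionMessage(e)),
                     class = c("eegsweep_training_error", "eegsweep_error"))
      })
  }
  models <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(G), train_one, mc.cores = workers)
  } else {
    lapply(seq_len(G), train_one)
  }
  structure(list(models = models, h = pairs$h, G = G, fs = pairs$fs,
                 n_channels = pairs$n_channels, scale = scale,
                 hidden_sizes = hidden_sizes,
                 final_loss = vapply(models, function(m) m$loss[length(m$loss)], 0)),
            class = "interpolator_ensemble")
}

#' @export
print.interpolator_ensemble <- function(x, ...) {
  cat(sprintf("<interpolator_ensemble> G = %d offsets, h = %d, %d channels @ %g Hz\n",
              x$G, x$h, x$n_channels, x$fs))
  cat(sprintf("  final loss: median %.4g (scaled units)\n", stats::median(x$final_loss)))
  invisible(x)
}

#' Predict the missing gap from its two context stacks
#'
#' Applies each offset network to the flattened `2h`-sample context.
#'
#' @param ens an `interpolator_ensemble`.
#' @param left,right channels-by-h matrices flanking the gap.
#' @return A channels-by-G matrix of predicted samples.
#' @export
predict_gap <- function(ens, left, right) {
  if (is.null(dim(left)) || is.null(dim(right)) ||
      !all(dim(left) == c(ens$n_channels, ens$h)) ||
      !all(dim(right) == c(ens$n_channels, ens$h)))
    stop_contract("context shapes must be channels x h matching the ensemble")
  x <- matrix(c(left, right), nrow = 1L) / ens$scale
  out <- vapply(seq_len(ens$G),
                function(q) as.numeric(nn_predict(ens$models[[q]], x)) * ens$scale,
                numeric(ens$n_channels))
  matrix(out, nrow = ens$n_channels)
}

#' Locate the most artifact-like G-sample segment of an epoch
#'
#' Slides a `G`-sample window over the summed absolute deviation from each
#' channel's median and returns the maximizing window, clamped so that both
#' h-sample context stacks fit inside the epoch. Coordinates follow the
#' package's 0-based half-open convention: the gap occupies
#' `[t_b + 1, t_e - 1]`, i.e. samples `t_b+1 .. t_b+G` (0-based).
#'
#' @param ep channels-by-samples matrix.
#' @param G gap length in samples.
#' @param h context half-width in samples.
#' @return A list `(t_b, t_e, G, h)`: `t_b` is the last clean sample before
#'   the gap and `t_e` the first clean sample after it (0-based).
#' @export
locate_artifact_segment <- function(ep, G, h) {
  ns <- ncol(ep)
  if (ns < 2L * h + G) stop_param("epoch too short for the requested gap and context")
  dev <- colSums(abs(ep - apply(ep, 1L, stats::median)))
  cs <- c(0, cumsum(dev))
  starts <- 1L:(ns - G + 1L)                     # 1-based candidate gap starts
  wsum <- cs[starts + G] - cs[starts]
  # find the most deviant window anywhere, then clamp it so both h-sample
  # context stacks fit inside the epoch
  s <- starts[which.max(wsum)]
  s <- min(max(s, h + 1L), ns - G - h + 1L)
  g0 <- s - 1L                                   # 0-based gap start
  list(t_b = g0 - 1L, t_e = g0 + G, G = G, h = h)
}

#' Correct flagged epochs by gap interpolation
#'
#' For every epoch flagged in the detection result: locate the most deviant
#' `G`-sample segment, predict it from the flanking contexts with the
#' ensemble, and splice the prediction in. All other samples — and all
#' unflagged epochs — are bit-identical to the input. A correction record is
#' appended to the output's metadata.
#'
#' @param es the [epoch_set()] to correct.
#' @param det an `artifact_detection` tibble from [run_detection()] (or any
#'   tibble with `epoch_index` and `flag`).
#' @param ens a trained `interpolator_ensemble` with matching geometry.
#' @return A corrected `epoch_set`; `metadata$corrections` is a tibble of
#'   `(epoch_index, start, end, skipped)` with 0-based half-open intervals.
#' @export
correct_epochs <- function(es, det, ens) {
  stopifnot(inherits(es, "epoch_set"))
  if (ens$n_channels != n_channels(es) || ens$fs != es$fs)
    stop_contract("ensemble geometry (channels/fs) does not match the epoch set")
  out <- es
  flagged <- det$epoch_index[det$flag]
  recs <- vector("list", length(flagged))
  for (k in seq_along(flagged)) {
    i <- flagged[k]
    ep <- epoch_data(es, i)
    if (ncol(ep) < 2L * ens$h + ens$G) {
      recs[[k]] <- tibble::tibble(epoch_index = i, start = NA_integer_,
                                  end = NA_integer_, skipped = TRUE)
      next
    }
    gap <- locate_artifact_segment(ep, ens$G, ens$h)
    g1 <- gap$t_b + 2L                           # 1-based first gap sample
    left <- ep[, (g1 - ens$h):(g1 - 1L), drop = FALSE]
    right <- ep[, (g1 + ens$G):(g1 + ens$G + ens$h - 1L), drop = FALSE]
    out$data[i, , g1:(g1 + ens$G - 1L)] <- predict_gap(ens, left, right)
    recs[[k]] <- tibble::tibble(epoch_index = i, start = gap$t_b + 1L,
                                end = gap$t_e, skipped = FALSE)
  }
  out$metadata$corrections <- dplyr::bind_rows(recs)
  out
}
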