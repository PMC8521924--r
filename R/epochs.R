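#' Epoched multichannel EEG container
#'
#' `epoch_set()` builds the central container the whole pipeline consumes: a
#' homogeneous collection of epochs (trials), each a channels-by-samples slab
#' of microvolt values at a shared sampling rate, with optional condition
#' labels, artifact annotations and subject identifiers. Epoch order is stable
#' and preserved by every transform in the package.
#'
#' @param data numeric array `[n_epochs, n_channels, n_samples]` in microvolts,
#'   or a list of equally shaped channels-by-samples matrices.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names optional character vector of channel identifiers.
#' @param labels optional per-epoch condition labels (integer; `NA` = unknown).
#' @param artifact_flags optional per-epoch expert/ground-truth artifact
#'   annotations (logical; `NA` = unannotated).
#' @param subject_ids optional per-epoch subject identifiers (character).
#' @param metadata free-form provenance list.
#' @return An object of class `epoch_set`.
#' @examples
#' es <- epoch_set(array(rnorm(5 * 2 * 100), c(5, 2, 100)), fs = 100)
#' n_epochs(es)
#' @export
epoch_set <- function(data, fs, channel_names = NULL, labels = NULL,
                      artifact_flags = NULL, subject_ids = NULL,
                      metadata = list()) {
  if (is.list(data) && !is.array(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L) stop_contract("all epochs must share the same channels x samples shape")
    arr <- array(0, c(length(data), dims[[1L]][1L], dims[[1L]][2L]))
    for (i in seq_along(data)) arr[i, , ] <- data[[i]]
    data <- arr
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_contract("`data` must be an [epochs, channels, samples] array")
  if (!all(is.finite(data))) stop_contract("epoch data must be finite")
  if (!is_scalar_number(fs) || fs <= 0) stop_param("`fs` must be a positive number")
  ne <- dim(data)[1L]
  structure(list(
    data = data,
    fs = fs,
    channel_names = channel_names %||% paste0("ch", seq_len(dim(data)[2L])),
    labels = as.integer(labels %||% rep(NA_integer_, ne)),
    artifact_flags = as.logical(artifact_flags %||% rep(NA, ne)),
    subject_ids = as.character(subject_ids %||% rep("s1", ne)),
    metadata = metadata
  ), class = "epoch_set")
}

#' @rdname epoch_set
#' @param es,x an `epoch_set`.
#' @export
n_epochs <- function(es) dim(es$data)[1L]

#' @rdname epoch_set
#' @export
n_channels <- function(es) dim(es$data)[2L]

#' @rdname epoch_set
#' @export
n_samples <- function(es) dim(es$data)[3L]

#' @rdname epoch_set
#' @param i epoch index (1-based row identity).
#' @export
epoch_data <- function(es, i) {
  m <- matrix(es$data[i, , ], nrow = dim(es$data)[2L])
  rownames(m) <- es$channel_names
  m
}

#' Subset an epoch set by epoch index, preserving order and annotations
#' @param es an `epoch_set`.
#' @param idx integer vector of epoch indices (1-based).
#' @export
subset_epochs <- function(es, idx) {
  epoch_set(es$data[idx, , , drop = FALSE], es$fs, es$channel_names,
            es$labels[idx], es$artifact_flags[idx], es$subject_ids[idx],
            es$metadata)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              n_epochs(x), n_channels(x), n_samples(x), x$fs))
  cat(sprintf("  labels: %d distinct | artifact flags: %d TRUE, %d NA | subjects: %d\n",
              length(unique(stats::na.omit(x$labels))),
              sum(x$artifact_flags, na.rm = TRUE), sum(is.na(x$artifact_flags)),
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Per-epoch metadata as a tibble
#'
#' One row per epoch: index, subject, condition label and artifact annotation.
#' @param es an `epoch_set`.
#' @export
epoch_info <- function(es) {
  tibble::tibble(
    epoch_index = seq_len(n_epochs(es)),
    subject_id = es$subject_ids,
    label = es$labels,
    artifact_flag = es$artifact_flags
  )
}

#' @method as_tibble epoch_set
#' @export
as_tibble.epoch_set <- function(x, ...) {
  ne <- n_epochs(x); nc <- n_channels(x); ns <- n_samples(x)
  tibble::tibble(
    epoch_index = rep(seq_len(ne), each = nc * ns),
    channel = rep(rep(x$channel_names, each = ns), times = ne),
    time = rep((seq_len(ns) - 1) / x$fs, times = ne * nc),
    value = as.vector(aperm(x$data, c(3L, 2L, 1L)))
  )
}

#' Segment a continuous recording into fixed-length epochs around events
#'
#' Cuts one epoch per matching event, spanning the half-open sample window
#' `[event - round(t_before * fs), event + round(t_after * fs))` in the
#' recording's 0-based sample coordinates. Events whose window would cross a
#' recording edge are dropped and counted in `metadata$dropped_count`.
#'
#' @param rec a recording as returned by [read_edf()].
#' @param event_label label of the events to epoch around.
#' @param t_before,t_after window extent in seconds before/after the event.
#' @return An [epoch_set()].
#' @export
epoch_continuous <- function(rec, event_label, t_before, t_after) {
  if (t_before + t_after <= 0) stop_param("t_before + t_after must be positive")
  ev <- rec$events[rec$events$label == event_label, , drop = FALSE]
  if (nrow(ev) == 0L) stop_param(sprintf("no events labelled '%s'", event_label))
  nb <- as.integer(round(t_before * rec$fs))
  na_ <- as.integer(round(t_after * rec$fs))
  ns <- ncol(rec$signals)
  start0 <- ev$sample - nb          # 0-based inclusive start
  end0 <- ev$sample + na_           # 0-based exclusive end
  keep <- start0 >= 0L & end0 <= ns
  dropped <- sum(!keep)
  if (!any(keep)) stop_param("all matching events fall outside the recording")
  idx <- which(keep)
  len <- nb + na_
  arr <- array(0, c(length(idx), nrow(rec$signals), len))
  for (k in seq_along(idx)) {
    arr[k, , ] <- rec$signals[, (start0[idx[k]] + 1L):(end0[idx[k]]), drop = FALSE]
  }
  epoch_set(arr, rec$fs, rec$channel_names,
            metadata = list(event_label = event_label, dropped_count = dropped,
                            t_before = t_before, t_after = t_after,
                            event_samples = ev$sample[keep]))
}

# Fourier-domain resampling of one vector to length m: truncate or zero-pad
# the spectrum, with the usual split/fold of the Nyquist bin.
.fourier_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  k <- min(m, n)
  if (k %% 2L == 0L) {
    h <- k %/% 2L
    Y[1:h] <- X[1:h]
    if (h > 1L) Y[(m - h + 2L):m] <- X[(n - h + 2L):n]
    if (m > n) {                       # upsample: split the Nyquist bin
      Y[h + 1L] <- X[h + 1L] / 2
      Y[m - h + 1L] <- Conj(X[h + 1L]) / 2
    } else {                           # downsample: fold +/- Nyquist
      Y[h + 1L] <- X[h + 1L] + X[n - h + 1L]
    }
  } else {
    h <- (k - 1L) %/% 2L
    Y[1:(h + 1L)] <- X[1:(h + 1L)]
    if (h > 0L) Y[(m - h + 1L):m] <- X[(n - h + 1L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample every epoch to a new sampling rate
#'
#' Fourier-domain resampling channel by channel (exact for band-limited
#' signals). The new epoch length is `round(n_samples * target_fs / fs)`;
#' labels, artifact flags and subject ids are carried through unchanged.
#' Upsampling is allowed but emits a warning.
#'
#' @param es an `epoch_set`.
#' @param target_fs target rate in Hz.
#' @export
resample_epochs <- function(es, target_fs) {
  if (!is_scalar_number(target_fs) || target_fs <= 0) stop_param("`target_fs` must be positive")
  if (target_fs == es$fs) return(es)
  if (target_fs > es$fs) warning("upsampling beyond the original rate", call. = FALSE)
  ns_new <- as.integer(round(n_samples(es) * target_fs / es$fs))
  arr <- array(0, c(n_epochs(es), n_channels(es), ns_new))
  for (i in seq_len(n_epochs(es))) {
    for (c in seq_len(n_channels(es))) {
      arr[i, c, ] <- .fourier_resample(es$data[i, c, ], ns_new)
    }
  }
  out <- epoch_set(arr, target_fs, es$channel_names, es$labels,
                   es$artifact_flags, es$subject_ids, es$metadata)
  out$metadata$resampled_from <- es$fs
  out
}

#' Zero-phase Butterworth band-pass filter across an epoch set
#'
#' Forward-backward (zero-phase) IIR filtering of every channel of every
#' epoch. `lo = 0` requests a low-pass.
#'
#' @param es an `epoch_set`.
#' @param lo,hi band edges in Hz; `0 <= lo < hi < fs/2`.
#' @param order Butterworth order (default 4, standard qEEG practice).
#' @export
bandpass_filter <- function(es, lo, hi, order = 4L) {
  nyq <- es$fs / 2
  if (lo < 0 || lo >= hi) stop_param("need 0 <= lo < hi")
  if (hi >= nyq) stop_param(sprintf("hi (%g Hz) must be below the Nyquist rate (%g Hz)", hi, nyq))
  bf <- if (lo == 0) signal::butter(order, hi / nyq, type = "low")
        else signal::butter(order, c(lo, hi) / nyq, type = "pass")
  arr <- es$data
  for (i in seq_len(n_epochs(es))) {
    for (c in seq_len(n_channels(es))) {
      arr[i, c, ] <- signal::filtfilt(bf, es$data[i, c, ])
    }
  }
  out <- es
  out$data <- arr
  out
}

.store_version <- 1L

#' Save / load an epoch set as a single-file container
#'
#' A versioned single-file container holding the arrays and annotation fields
#' (`data`, `fs`, `channels`, `labels`, `artifact_flags`, `subject_ids`,
#' `metadata`). `load_store(save_store(es, path))` is the identity on every
#' field; a version mismatch or a corrupted file raises a format error.
#'
#' @param es an `epoch_set`.
#' @param path file path.
#' @return `save_store()` returns `path` invisibly; `load_store()` returns the
#'   `epoch_set`.
#' @export
save_store <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  obj <- list(format = "eegsweep_epoch_store", version = .store_version,
              data = es$data, fs = es$fs, channels = es$channel_names,
              labels = es$labels, artifact_flags = es$artifact_flags,
              subject_ids = es$subject_ids, metadata = es$metadata)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_format(sprintf("cannot read epoch store '%s': %s", path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, "eegsweep_epoch_store"))
    stop_format(sprintf("'%s' is not an epoch store", path))
  if (!identical(obj$version, .store_version))
    stop_format(sprintf("epoch store version mismatch: found %s, expected %s",
                        obj$version, .store_version))
  epoch_set(obj$data, obj$fs, obj$channels, obj$labels, obj$artifact_flags,
            obj$subject_ids, obj$metadata)
}
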