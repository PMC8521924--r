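# European Data Format (EDF/EDF+) support. Hand-written binary parser: the
# header is plain ASCII in fixed-width fields, signal data are little-endian
# 16-bit integers mapped linearly from the digital to the physical range.
# Only the subset of EDF+ needed here is supported: one optional
# "EDF Annotations" channel whose time-stamped annotation lists (TALs) are
# mapped to events.

.edf_field <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1L):(off + len)]))
}

.edf_num <- function(raw, off, len, what) {
  v <- suppressWarnings(as.numeric(.edf_field(raw, off, len)))
  if (is.na(v)) stop_format(sprintf("EDF header field '%s' is not numeric", what))
  v
}

#' Read an EDF/EDF+ file
#'
#' Returns a continuous recording: a channels-by-samples signal matrix
#' converted to microvolts (mV and V physical dimensions are rescaled), the
#' sampling rate, channel names, and an event table parsed from the
#' EDF+ annotations channel when present. Event samples are 0-based indices
#' into the signal matrix.
#'
#' All regular signals must share one sampling rate (the usual case for
#' epoched EEG work); mixed-rate files raise a format error.
#'
#' @param path path to an EDF file.
#' @return A list of class `eeg_recording` with elements `signals` (matrix,
#'   microvolts), `fs` (Hz), `channel_names`, and `events` (tibble with
#'   0-based `sample` and `label`).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("EDF file '%s' does not exist", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop_format("EDF file is too short to hold the 256-byte header (field 'version')")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", 256L)
  n_rec <- .edf_num(hdr, 236, 8, "number of data records")
  rec_dur <- .edf_num(hdr, 244, 8, "data record duration")
  ns <- as.integer(.edf_num(hdr, 252, 4, "number of signals"))
  if (ns < 1L) stop_format("EDF header field 'number of signals' must be >= 1")
  if (sz < 256 + ns * 256) stop_format("EDF file truncated inside the signal header (field 'label')")
  shdr <- readBin(con, "raw", 256L * ns)
  # signal header layout: label 16, transducer 80, dim 8, phys min 8,
  # phys max 8, dig min 8, dig max 8, prefilter 80, samples/record 8
  labels <- vapply(seq_len(ns) - 1L, function(i) .edf_field(shdr, i * 16L, 16L), "")
  base <- 16L * ns + 80L * ns
  dims <- vapply(seq_len(ns) - 1L, function(i) .edf_field(shdr, base + i * 8L, 8L), "")
  num_col <- function(col_off, what) {
    vapply(seq_len(ns) - 1L, function(i) .edf_num(shdr, col_off + i * 8L, 8L, what), 0)
  }
  pmin_ <- num_col(base + 8L * ns, "physical minimum")
  pmax_ <- num_col(base + 16L * ns, "physical maximum")
  dmin_ <- num_col(base + 24L * ns, "digital minimum")
  dmax_ <- num_col(base + 32L * ns, "digital maximum")
  spr <- as.integer(num_col(base + 40L * ns + 80L * ns, "samples per record"))
  if (any(spr < 1L)) stop_format("EDF header field 'samples per record' must be positive")

  is_annot <- labels == "EDF Annotations"
  if (all(is_annot)) stop_format("EDF file contains no regular signals (field 'label')")
  if (n_rec < 0) stop_format("EDF header field 'number of data records' is negative")

  need <- n_rec * sum(spr) * 2
  payload <- readBin(con, "raw", need)
  if (length(payload) < need)
    stop_format("EDF file truncated: fewer data records than the header announces (field 'number of data records')")

  reg <- which(!is_annot)
  fs_all <- spr[reg] / rec_dur
  if (length(unique(fs_all)) != 1L)
    stop_format("mixed per-signal sampling rates are not supported (field 'samples per record')")
  fs <- fs_all[1L]

  # physical unit -> microvolts
  unit_scale <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1)
  }, 0)
  gain <- (pmax_ - pmin_) / pmax(dmax_ - dmin_, 1)

  sig <- matrix(0, nrow = length(reg), ncol = n_rec * spr[reg[1L]])
  annot_raw <- raw(0)
  offs <- c(0L, cumsum(spr * 2L))
  for (r in seq_len(n_rec)) {
    rec0 <- (r - 1L) * sum(spr) * 2L
    for (j in seq_len(ns)) {
      bytes <- payload[(rec0 + offs[j] + 1L):(rec0 + offs[j + 1L])]
      if (is_annot[j]) {
        annot_raw <- c(annot_raw, bytes)
      } else {
        dig <- readBin(bytes, integer(), n = spr[j], size = 2L, signed = TRUE, endian = "little")
        k <- match(j, reg)
        phys <- (dig - dmin_[j]) * gain[j] + pmin_[j]
        sig[k, ((r - 1L) * spr[j] + 1L):(r * spr[j])] <- phys * unit_scale[j]
      }
    }
  }

  events <- .parse_tal(annot_raw, fs)
  structure(list(signals = sig, fs = fs, channel_names = labels[reg],
                 events = events),
            class = "eeg_recording")
}

# Parse EDF+ time-stamped annotation lists. Onsets are seconds; record
# keep-alive stamps (empty labels) are dropped.
.parse_tal <- function(bytes, fs) {
  out <- tibble::tibble(sample = integer(0), label = character(0))
  if (length(bytes) == 0L) return(out)
  nul <- which(bytes == as.raw(0L))
  starts <- c(1L, nul + 1L)
  ends <- c(nul - 1L, length(bytes))
  samples <- integer(0); labs <- character(0)
  for (k in seq_along(starts)) {
    if (ends[k] < starts[k]) next
    txt <- rawToChar(bytes[starts[k]:ends[k]])
    parts <- strsplit(txt, "\x14", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) next
    onset <- suppressWarnings(as.numeric(strsplit(parts[1L], "\x15", fixed = TRUE)[[1L]][1L]))
    if (is.na(onset)) next
    for (lab in parts[-1L]) {
      if (nzchar(lab)) {
        samples <- c(samples, as.integer(round(onset * fs)))
        labs <- c(labs, lab)
      }
    }
  }
  tibble::tibble(sample = samples, label = labs)
}

.edf_pad <- function(x, len) {
  x <- substr(x, 1L, len)
  paste0(x, strrep(" ", len - nchar(x)))
}

#' Write a recording to an EDF(+) file
#'
#' Minimal EDF writer, primarily for building interoperable fixtures and for
#' exporting simulated recordings. Signals are quantized to 16-bit over the
#' given physical range; events (if any) are written as an EDF Annotations
#' channel. The number of samples must be a multiple of `fs` (whole 1-second
#' data records).
#'
#' @param rec an `eeg_recording` (list with `signals`, `fs`, `channel_names`,
#'   optional `events`), or an object accepted by the same contract.
#' @param path output path.
#' @param phys_min,phys_max physical range per channel (recycled); defaults to
#'   a symmetric range covering the data.
#' @param dim physical dimension string written to the header (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_min = NULL, phys_max = NULL, dim = "uV") {
  sig <- rec$signals
  fs <- rec$fs
  nc <- nrow(sig); ns <- ncol(sig)
  if (ns %% fs != 0) stop_param("number of samples must be a whole number of 1-second records")
  n_rec <- ns / fs
  amax <- max(abs(sig), 1e-6)
  phys_max <- rep(phys_max %||% ceiling(amax), length.out = nc)
  phys_min <- rep(phys_min %||% -ceiling(amax), length.out = nc)
  dmin <- -32768; dmax <- 32767
  events <- rec$events
  has_annot <- !is.null(events) && nrow(events) > 0L
  annot_spr <- 32L  # 64 bytes per record

  ntot <- nc + has_annot
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(x, len) writeChar(.edf_pad(x, len), con, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("eegsweep fixture", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ntot)), 8)
  wr(if (has_annot) "EDF+C" else "", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ntot), 4)
  labs <- c(rec$channel_names %||% paste0("ch", seq_len(nc)),
            if (has_annot) "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ntot)) wr("", 80)                       # transducer
  for (i in seq_len(ntot)) wr(if (i <= nc) dim else "", 8)  # physical dim
  for (i in seq_len(ntot)) wr(as.character(if (i <= nc) phys_min[i] else -1), 8)
  for (i in seq_len(ntot)) wr(as.character(if (i <= nc) phys_max[i] else 1), 8)
  for (i in seq_len(ntot)) wr(as.character(dmin), 8)
  for (i in seq_len(ntot)) wr(as.character(dmax), 8)
  for (i in seq_len(ntot)) wr("", 80)                       # prefiltering
  for (i in seq_len(ntot)) wr(as.character(if (i <= nc) fs else annot_spr), 8)
  for (i in seq_len(ntot)) wr("", 32)                       # reserved

  for (r in seq_len(n_rec)) {
    for (c in seq_len(nc)) {
      x <- sig[c, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((x - phys_min[c]) / (phys_max[c] - phys_min[c]) * (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
    if (has_annot) {
      # each TAL is "<onset>\x14<label>\x14" terminated by a nul byte
      tals <- sprintf("+%d\x14\x14", r - 1L)
      ev <- events[events$sample >= (r - 1) * fs & events$sample < r * fs, , drop = FALSE]
      if (nrow(ev) > 0L) {
        tals <- c(tals, sprintf("+%g\x14%s\x14", ev$sample / fs, ev$label))
      }
      buf <- unlist(lapply(tals, function(t) c(charToRaw(t), as.raw(0L))))
      if (length(buf) > annot_spr * 2L) stop_param("too many events in one record for the writer")
      buf <- c(buf, raw(annot_spr * 2L - length(buf)))
      writeBin(buf, con)
    }
  }
  invisible(path)
}
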