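#' Epoch set
#'
#' A stack of fixed-length multichannel epochs from one subject and recording
#' condition, all sharing shape, sampling rate and channel order. An optional
#' band tag marks the set as band-pass filtered.
#'
#' @param epochs List of channels x samples numeric matrices, all the same shape.
#' @param fs Sampling rate in Hz.
#' @param channel_labels One label per matrix row.
#' @param subject_id,condition Optional provenance tags carried through the
#'   pipeline into measure records.
#' @param band Optional [band_definition()] tag set by [bandpass()].
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, channel_labels,
                      subject_id = NA_character_, condition = NA_character_,
                      band = NULL) {
  stopifnot(is.list(epochs))
  channel_labels <- as.character(channel_labels)
  fs <- as.numeric(fs)
  stopifnot(is.finite(fs), fs > 0)
  if (length(epochs)) {
    dims <- vapply(epochs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all epochs must share the same channels x samples shape")
    if (dims[1, 1] != length(channel_labels))
      stop("epoch has ", dims[1, 1], " rows but ", length(channel_labels),
           " channel labels were given")
    if (any(vapply(epochs, function(e) any(!is.finite(e)), logical(1))))
      stop("epochs contain non-finite samples")
    epochs <- lapply(epochs, function(e) {
      rownames(e) <- channel_labels
      e
    })
  }
  if (!is.null(band)) stopifnot(inherits(band, "band_definition"))
  structure(list(epochs = epochs, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, condition = condition, band = band),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  ns <- if (length(x$epochs)) ncol(x$epochs[[1]]) else 0L
  cat(sprintf("<epoch_set> %d epoch(s) of %d channels x %d samples @ %g Hz%s\n",
              length(x$epochs), length(x$channel_labels), ns, x$fs,
              if (is.null(x$band)) " (broadband)"
              else sprintf(" [%s %g-%g Hz]", x$band$name, x$band$low, x$band$high)))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es An [epoch_set()].
#' @return Integer count.
#' @export
n_epochs <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  length(es$epochs)
}

#' Cut contiguous non-overlapping epochs from a continuous record
#'
#' Takes `n_epochs` back-to-back windows of `epoch_len` samples starting at
#' `offset` (0-based) -- epochs are taken from the start of the recording by
#' default. Sample values are copied bit-exactly; no resampling or filtering.
#'
#' @param record An [eeg_record()].
#' @param n_epochs Number of windows; 0 gives an empty epoch set.
#' @param epoch_len Window length in samples (default 4096).
#' @param offset 0-based sample offset of the first window.
#' @param subject_id,condition Provenance tags for the resulting set.
#' @return An [epoch_set()] (broadband: no band tag).
#' @export
select_epochs <- function(record, n_epochs = 4L, epoch_len = 4096L, offset = 0L,
                          subject_id = NA_character_, condition = NA_character_) {
  stopifnot(inherits(record, "eeg_record"))
  n_epochs <- as.integer(n_epochs); epoch_len <- as.integer(epoch_len)
  offset <- as.integer(offset)
  stopifnot(n_epochs >= 0L, epoch_len > 0L, offset >= 0L)
  need <- offset + n_epochs * epoch_len
  have <- ncol(record$data)
  if (have < need)
    stop("record too short: need ", need, " samples (offset ", offset, " + ",
         n_epochs, " x ", epoch_len, "), have ", have,
         " (short by ", need - have, ")")
  eps <- lapply(seq_len(n_epochs), function(k) {
    i0 <- offset + (k - 1L) * epoch_len
    record$data[, (i0 + 1L):(i0 + epoch_len), drop = FALSE]
  })
  epoch_set(eps, record$fs, record$labels,
            subject_id = subject_id, condition = condition)
}

#' Zero-phase band-pass filter an epoch set
#'
#' Each channel of each epoch is filtered forward and backward with a
#' 4th-order Butterworth band-pass (8th-order magnitude response, zero net
#' phase). Zero phase distortion matters here: downstream phase-lag estimates
#' would be biased by any frequency-dependent delay. Output length equals
#' input length.
#'
#' @param es An [epoch_set()].
#' @param band A [band_definition()]; `band$high` must be below the Nyquist
#'   frequency `fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered [epoch_set()], tagged with `band`.
#' @export
bandpass <- function(es, band, order = 4L) {
  stopifnot(inherits(es, "epoch_set"), inherits(band, "band_definition"))
  nyq <- es$fs / 2
  if (band$high >= nyq)
    stop("band upper edge (", band$high, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  bf <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  eps <- lapply(es$epochs, function(e) {
    t(apply(e, 1L, function(x) signal::filtfilt(bf, x)))
  })
  epoch_set(eps, es$fs, es$channel_labels,
            subject_id = es$subject_id, condition = es$condition, band = band)
}

#' Apply a montage to every epoch of an epoch set
#'
#' Convenience wrapper: drops excluded channels, reorders and average-
#' references each epoch independently (the average reference is a per-sample
#' operation, so per-epoch application equals whole-record application).
#'
#' @param es An [epoch_set()].
#' @param m A [montage()].
#' @return An [epoch_set()] on the montage's retained channels.
#' @export
apply_montage_epochs <- function(es, m = default_montage()) {
  stopifnot(inherits(es, "epoch_set"))
  eps <- lapply(es$epochs, function(e) {
    r <- apply_montage(eeg_record(e, es$channel_labels, es$fs), m)
    r$data
  })
  epoch_set(eps, es$fs, montage_channels(m),
            subject_id = es$subject_id, condition = es$condition, band = es$band)
}
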