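#' Electrode montage
#'
#' A montage lists the electrodes of a recording in canonical order, the
#' re-referencing scheme (only the common average is supported) and the
#' electrodes to drop before network construction.
#'
#' @param channel_labels Character vector of unique electrode names, in
#'   canonical order.
#' @param reference Referencing scheme; only `"average"` is supported.
#' @param excluded Labels to drop; must be a subset of `channel_labels`.
#' @return An object of class `montage`.
#' @seealso [default_montage()] for the standard 21-electrode 10-20 layout.
#' @export
montage <- function(channel_labels, reference = "average", excluded = character()) {
  channel_labels <- as.character(channel_labels)
  excluded <- as.character(excluded)
  if (anyDuplicated(channel_labels))
    stop("montage channel labels must be unique")
  if (!all(excluded %in% channel_labels))
    stop("excluded labels not in montage: ",
         paste(setdiff(excluded, channel_labels), collapse = ", "))
  reference <- match.arg(reference, "average")
  structure(list(channel_labels = channel_labels, reference = reference,
                 excluded = excluded),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels (%d excluded), %s reference\n",
              length(x$channel_labels), length(x$excluded), x$reference))
  invisible(x)
}

#' Retained channels of a montage
#'
#' @param m A [montage()].
#' @return Character vector of labels kept after exclusion, in montage order.
#' @export
montage_channels <- function(m) {
  stopifnot(inherits(m, "montage"))
  setdiff(m$channel_labels, m$excluded)
}

#' Standard 21-electrode clinical montage
#'
#' The international 10-20 scalp layout with 21 electrodes. The two
#' frontopolar and the two ear (basal temporal) electrodes -- Fp1, Fp2, A1,
#' A2 -- are excluded by default because they are the most artifact-prone,
#' leaving 17 electrodes as network nodes.
#'
#' @param exclude_frontopolar_ear Drop Fp1, Fp2, A1 and A2 (default `TRUE`).
#' @return A [montage()] with 21 labels and, by default, 4 exclusions.
#' @examples
#' length(montage_channels(default_montage()))  # 17
#' @export
default_montage <- function(exclude_frontopolar_ear = TRUE) {
  labels <- c("Fp1", "Fp2", "F8", "F4", "Fz", "F3", "F7", "A2", "T8", "C4",
              "Cz", "C3", "T7", "A1", "P8", "P4", "Pz", "P3", "P7", "O1", "O2")
  excl <- if (exclude_frontopolar_ear) c("Fp1", "Fp2", "A1", "A2") else character()
  montage(labels, reference = "average", excluded = excl)
}

#' Raw multichannel record
#'
#' Thin container for a continuous multichannel recording: a channels-by-
#' samples numeric matrix with channel labels as row names, plus the sampling
#' rate.
#'
#' @param data Numeric matrix, channels x samples.
#' @param labels Channel labels, one per row of `data`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, labels, fs) {
  data <- as.matrix(data)
  labels <- as.character(labels)
  if (nrow(data) != length(labels))
    stop("number of rows of data (", nrow(data),
         ") != number of labels (", length(labels), ")")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (any(!is.finite(data))) stop("record contains non-finite samples")
  fs <- as.numeric(fs)
  stopifnot(is.finite(fs), fs > 0)
  rownames(data) <- labels
  structure(list(data = data, labels = labels, fs = fs), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Apply a montage: drop excluded channels and re-reference to the average
#'
#' Excluded channels are removed, the retained channels are reordered to the
#' montage's canonical order, and the instantaneous mean across retained
#' channels is subtracted from every channel (common average reference).
#'
#' @param record An [eeg_record()].
#' @param m A [montage()]; defaults to [default_montage()].
#' @return An [eeg_record()] on the retained channels, average-referenced.
#' @export
apply_montage <- function(record, m = default_montage()) {
  stopifnot(inherits(record, "eeg_record"), inherits(m, "montage"))
  keep <- montage_channels(m)
  missing <- setdiff(keep, record$labels)
  if (length(missing))
    stop("record is missing required channel(s): ",
         paste(missing, collapse = ", "))
  x <- record$data[keep, , drop = FALSE]
  ref <- colMeans(x)
  x <- sweep(x, 2L, ref, "-")
  eeg_record(x, keep, record$fs)
}
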