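# Phase Lag Index connectivity: analytic-signal phases, pairwise PLI,
# epoch-averaged matrices and relative band power.

#' Discrete analytic signal via the FFT
#'
#' Standard frequency-domain construction: zero the negative frequencies,
#' double the positive ones, keep DC (and Nyquist for even lengths).
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase is the argument of the analytic signal, sample-aligned with the
#' input. Because the discrete analytic signal is distorted near the record
#' ends, a number of edge samples at each end is flagged for exclusion from
#' downstream phase-difference averaging: one cycle of the band's lowest
#' frequency (`ceiling(fs / band_low)`), capped at 10% of the samples per
#' end.
#'
#' @param x Real numeric vector (band-limited samples of one channel).
#' @param fs Sampling rate in Hz.
#' @param band_low Lower band edge in Hz used to size the edge margin; if
#'   `NULL`, the 10% cap alone applies.
#' @param n_edge Explicit edge margin in samples, overriding the automatic
#'   choice.
#' @param label,band Optional provenance tags.
#' @return An object of class `phase_series`: fields `phase` (radians in
#'   `(-pi, pi]`), `fs`, `n_edge`, `label`, `band`.
#' @examples
#' t <- (0:511) / 512
#' ph <- instantaneous_phase(cos(2 * pi * 10 * t), 512, band_low = 8)
#' @export
instantaneous_phase <- function(x, fs, band_low = NULL, n_edge = NULL,
                                label = NA_character_, band = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (stats::sd(x) == 0)
    stop("constant input: instantaneous phase is undefined")
  if (is.null(n_edge)) {
    cap <- floor(0.1 * n)
    n_edge <- if (is.null(band_low)) cap else min(ceiling(fs / band_low), cap)
  }
  n_edge <- as.integer(n_edge)
  stopifnot(n_edge >= 0L, 2L * n_edge < n)
  structure(list(phase = Arg(analytic_signal(x)), fs = fs, n_edge = n_edge,
                 label = label, band = band),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz (%d edge samples/end flagged)\n",
              length(x$phase), x$fs, x$n_edge))
  invisible(x)
}

#' Wrap phase differences to (-pi, pi]
#'
#' @param x Radians.
#' @return Wrapped radians in `(-pi, pi]`.
#' @keywords internal
wrap_phase <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Phase Lag Index of two phase series
#'
#' `PLI = |mean(sign(dphi))|` over retained samples, with the instantaneous
#' phase difference `dphi` wrapped to `(-pi, pi]`. `sign(0)` contributes 0,
#' so coupling at exactly zero (or pi) lag -- the signature of volume
#' conduction at the scalp -- does not register. Edge-flagged samples (the
#' larger margin of the two inputs) are removed from both series
#' identically.
#'
#' @param pa,pb Two [instantaneous_phase()] series of equal length and rate,
#'   or plain numeric phase vectors.
#' @return A value in `[0, 1]`: 0 for no consistent nonzero lag, 1 for a
#'   perfectly consistent lag sign.
#' @examples
#' pli(c(0, 1, 2), c(0, 1, 2) - pi / 2)  # constant +pi/2 lag -> 1
#' @export
pli <- function(pa, pb) {
  as_ps <- function(p) {
    if (inherits(p, "phase_series")) p
    else list(phase = as.numeric(p), fs = NA_real_, n_edge = 0L)
  }
  pa <- as_ps(pa); pb <- as_ps(pb)
  if (length(pa$phase) != length(pb$phase))
    stop("phase series length mismatch: ", length(pa$phase), " vs ",
         length(pb$phase))
  if (!is.na(pa$fs) && !is.na(pb$fs) && pa$fs != pb$fs)
    stop("sampling rates differ")
  ne <- max(pa$n_edge, pb$n_edge)
  keep <- if (ne > 0L) seq.int(ne + 1L, length(pa$phase) - ne)
          else seq_along(pa$phase)
  d <- wrap_phase(pa$phase[keep] - pb$phase[keep])
  abs(mean(sign(d)))
}

#' Epoch-averaged PLI connectivity matrix
#'
#' For every epoch, pairwise PLI is computed between all channel pairs from
#' analytic-signal phases; the matrices are then averaged arithmetically
#' across epochs. The result is the symmetric zero-diagonal weight matrix of
#' the functional network.
#'
#' @param es A band-pass filtered [epoch_set()] with at least one epoch and
#'   two channels.
#' @return An object of class `connectivity_matrix`: fields `weights`
#'   (symmetric N x N in `[0, 1]`, zero diagonal, dimnames = labels),
#'   `labels`, `band`, `n_epochs_averaged`.
#' @export
pli_matrix <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  n <- length(es$channel_labels)
  if (n < 2L) stop("need at least 2 channels")
  if (!length(es$epochs)) stop("need at least 1 epoch")
  band_low <- if (!is.null(es$band)) es$band$low else NULL
  acc <- matrix(0, n, n)
  for (e in es$epochs) {
    ph <- lapply(seq_len(n), function(i)
      instantaneous_phase(e[i, ], es$fs, band_low = band_low))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- pli(ph[[i]], ph[[j]])
      acc[i, j] <- acc[i, j] + v
      acc[j, i] <- acc[j, i] + v
    }
  }
  w <- acc / length(es$epochs)
  dimnames(w) <- list(es$channel_labels, es$channel_labels)
  structure(list(weights = w, labels = es$channel_labels, band = es$band,
                 n_epochs_averaged = length(es$epochs)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d PLI%s, mean off-diagonal %.3f (%d epochs)\n",
              nrow(x$weights), ncol(x$weights),
              if (is.null(x$band)) "" else paste0(" [", x$band$name, "]"),
              mean(x$weights[upper.tri(x$weights)]), x$n_epochs_averaged))
  invisible(x)
}

# Accept either a connectivity_matrix or a plain symmetric matrix.
as_weight_matrix <- function(W) {
  if (inherits(W, "connectivity_matrix")) W <- W$weights
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (!isTRUE(all.equal(W, t(W), check.attributes = FALSE)))
    stop("weight matrix must be symmetric")
  if (any(diag(W) != 0)) stop("weight matrix diagonal must be zero")
  if (any(W < 0 | W > 1)) stop("weights must lie in [0, 1]")
  if (is.null(rownames(W)))
    dimnames(W) <- list(sprintf("n%02d", seq_len(nrow(W))),
                        sprintf("n%02d", seq_len(nrow(W))))
  W
}

#' Welch-style power spectral density of one channel
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram.
#'
#' @param x Samples.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @keywords internal
welch_psd <- function(x, fs, seg_len = min(length(x), 1024L)) {
  n <- length(x)
  seg_len <- min(as.integer(seg_len), n)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, seg_len - 1L) / (seg_len - 1L))
  u <- sum(win^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * win
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * u)
    # fold the negative-frequency half into the one-sided density
    if (seg_len %% 2L == 0L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = acc / length(starts))
}

#' Relative band power of a broadband epoch set
#'
#' Per epoch and channel, spectral power is integrated over each analysis
#' band (half-open `[low, high)` intervals, so adjacent bands do not double
#' count their shared edge) and divided by the power over the total analysis
#' band; fractions are then averaged over channels and epochs.
#'
#' @param es A broadband (unfiltered) [epoch_set()].
#' @param bands List of [band_definition()]s (default: the five power bands
#'   of [eeg_power_bands()]).
#' @param total_band Numeric `(low, high)` Hz denominator band; defaults to
#'   the union of the analysis bands, 0.5-30 Hz.
#' @param seg_len Welch segment length in samples.
#' @return Named numeric vector of band fractions in `[0, 1]`.
#' @export
relative_power <- function(es, bands = eeg_power_bands(),
                           total_band = c(0.5, 30),
                           seg_len = 1024L) {
  stopifnot(inherits(es, "epoch_set"))
  if (!is.null(es$band))
    warning("relative_power expects a broadband epoch set; input is tagged '",
            es$band$name, "'")
  if (!length(es$epochs)) stop("empty epoch set")
  nb <- length(bands)
  nm <- vapply(bands, `[[`, "", "name")
  acc <- numeric(nb)
  count <- 0L
  for (e in es$epochs) {
    for (i in seq_len(nrow(e))) {
      sp <- welch_psd(e[i, ], es$fs, seg_len)
      tot_idx <- sp$freq >= total_band[1] & sp$freq < total_band[2]
      tot <- sum(sp$psd[tot_idx])
      if (tot <= 0) stop("zero total power in channel ", i)
      for (b in seq_len(nb)) {
        idx <- sp$freq >= bands[[b]]$low & sp$freq < bands[[b]]$high
        acc[b] <- acc[b] + sum(sp$psd[idx]) / tot
      }
      count <- count + 1L
    }
  }
  stats::setNames(acc / count, nm)
}
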