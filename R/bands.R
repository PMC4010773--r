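#' Frequency band definition
#'
#' A band is a named half-open frequency interval `[low, high)` in Hz used for
#' band-pass filtering (connectivity analysis) and for integrating relative
#' spectral power.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low Lower edge in Hz; must be strictly positive.
#' @param high Upper edge in Hz; must exceed `low`.
#' @return An object of class `band_definition`.
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low)
    stop("band must satisfy 0 < low < high; got [", low, ", ", high, ")")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Connectivity analysis bands
#'
#' The four bands in which pairwise PLI networks are constructed:
#' delta (0.5-4 Hz), theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz).
#'
#' @return A named list of [band_definition()] objects.
#' @export
eeg_bands <- function() {
  list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30)
  )
}

#' Relative-power analysis bands
#'
#' The five bands used for relative power spectra; alpha is split into
#' alpha1 (8-10 Hz) and alpha2 (10-13 Hz).
#'
#' @return A named list of [band_definition()] objects.
#' @export
eeg_power_bands <- function() {
  list(
    delta  = band_definition("delta", 0.5, 4),
    theta  = band_definition("theta", 4, 8),
    alpha1 = band_definition("alpha1", 8, 10),
    alpha2 = band_definition("alpha2", 10, 13),
    beta   = band_definition("beta", 13, 30)
  )
}
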