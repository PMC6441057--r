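# Welch power spectral density, 1/f whitening, band power, line masking.

#' Canonical analysis bands
#'
#' Delta (1-4 Hz), theta (5-9 Hz), spindle (10-18 Hz) and high beta
#' (19-30 Hz).
#'
#' @return data.frame `name`, `lo_hz`, `hi_hz`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "spindle", "high_beta"),
             lo_hz = c(1, 5, 10, 19), hi_hz = c(4, 9, 18, 30),
             stringsAsFactors = FALSE)
}

new_spectrum <- function(freqs, psd, n_epochs = 1L, channel = NA_character_,
                         state = NA_character_, masked = NULL) {
  if (is.null(masked)) masked <- rep(FALSE, length(freqs))
  structure(list(freqs = freqs, psd = psd, masked = masked,
                 n_epochs_averaged = n_epochs, channel = channel, state = state),
            class = "sc_spectrum")
}

#' @export
print.sc_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bins, %.1f-%.1f Hz, %d epoch(s)%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_epochs_averaged,
              if (any(x$masked)) sprintf(", %d masked", sum(x$masked)) else ""))
  invisible(x)
}

#' Welch power spectral density of a signal segment
#'
#' One-sided density estimate from Hamming-windowed, mean-removed, 50%
#' overlapping segments.  Normalized so that the integral of the density over
#' frequency approximates the signal variance (Parseval).
#'
#' @param x numeric signal segment (microvolts).
#' @param fs sampling rate, Hz.
#' @param window_s Welch window length in seconds (default 2, giving 0.5 Hz
#'   resolution; a 20-s epoch yields 19 averaged segments).
#' @param overlap_frac fractional overlap between windows (default 0.5).
#' @param fmax optional upper frequency cut for the returned grid.
#' @param channel,state optional labels carried on the result.
#' @return an `sc_spectrum`: `freqs` (Hz), `psd` (uV^2/Hz), `masked`,
#'   `n_epochs_averaged`, `channel`, `state`.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap_frac = 0.5, fmax = NULL,
                      channel = NA_character_, state = NA_character_) {
  w <- welch_engine(x, fs = fs, window_s = window_s, overlap_frac = overlap_frac)
  keep <- if (is.null(fmax)) seq_along(w$freqs) else which(w$freqs <= fmax)
  new_spectrum(w$freqs[keep], w$pxx[keep], channel = channel, state = state)
}

#' Average spectra over epochs
#'
#' @param spectra list of `sc_spectrum` objects on identical frequency grids.
#' @return an `sc_spectrum` with `n_epochs_averaged` set to the total count.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  f0 <- spectra[[1]]$freqs
  for (s in spectra) {
    if (!isTRUE(all.equal(s$freqs, f0))) stop("integrity error: frequency grids differ")
  }
  psd <- rowMeans(vapply(spectra, function(s) s$psd, numeric(length(f0))))
  masked <- Reduce(`|`, lapply(spectra, function(s) s$masked))
  new_spectrum(f0, psd, n_epochs = sum(vapply(spectra, function(s)
    s$n_epochs_averaged, numeric(1))), channel = spectra[[1]]$channel,
    state = spectra[[1]]$state, masked = masked)
}

#' Whiten a spectrum by multiplying with frequency
#'
#' Flattens the 1/f background for display and band comparison:
#' `psd_out(f) = f * psd_in(f)`.
#'
#' @param s an `sc_spectrum`.
#' @return the whitened `sc_spectrum`.
#' @export
whiten_spectrum <- function(s) {
  stopifnot(inherits(s, "sc_spectrum"))
  s$psd <- s$freqs * s$psd
  s
}

#' Band power by trapezoidal integration
#'
#' @param s an `sc_spectrum`.
#' @param lo_hz,hi_hz band edges (must lie within the spectrum range); a band
#'   row from [band_definitions()] can be given as `lo_hz`.
#' @return scalar power (uV^2); masked bins inside the band are excluded from
#'   the integration grid.
#' @export
band_power <- function(s, lo_hz, hi_hz = NULL) {
  stopifnot(inherits(s, "sc_spectrum"))
  if (is.null(hi_hz)) { hi_hz <- lo_hz$hi_hz; lo_hz <- lo_hz$lo_hz }
  if (lo_hz >= hi_hz || lo_hz < min(s$freqs) || hi_hz > max(s$freqs)) {
    stop("input error: band outside spectrum range")
  }
  i <- which(s$freqs >= lo_hz & s$freqs <= hi_hz & !s$masked)
  if (length(i) < 2) stop("input error: fewer than two unmasked bins in band")
  f <- s$freqs[i]; p <- s$psd[i]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Mask line-frequency bins
#'
#' Flags bins within `line_hz` +/- `half_width_hz` as excluded; masked bins
#' are dropped from band integrals, band coherence averages, and group
#' statistics.  With `half_width_hz = 0` only the nearest bin is masked.
#'
#' @param s an `sc_spectrum` or `sc_coherence`.
#' @param line_hz line frequency (default 50).
#' @param half_width_hz half-width of the mask in Hz (default 1).
#' @return the object with its `masked` field updated.
#' @export
notch_mask <- function(s, line_hz = 50, half_width_hz = 1) {
  stopifnot(inherits(s, c("sc_spectrum", "sc_coherence")))
  if (half_width_hz <= 0) {
    i <- which.min(abs(s$freqs - line_hz))
  } else {
    i <- which(abs(s$freqs - line_hz) <= half_width_hz)
  }
  s$masked[i] <- TRUE
  s
}
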