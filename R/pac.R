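# Phase-amplitude coupling: Kullback-Leibler modulation index, comodulogram,
# and the high-coupling-region summary compared between groups.

# Phase and amplitude-envelope series for one segment, edge-trimmed to drop
# filter transients.
.phase_amp <- function(x, fs, phase_band, amp_band, trim_s = 0.25) {
  ph <- Arg(analytic_signal(bp_filter(x, fs, phase_band[1], phase_band[2],
                                      trans_hz = 0.5)))
  am <- Mod(analytic_signal(bp_filter(x, fs, amp_band[1], amp_band[2])))
  n <- length(x)
  keep <- (round(trim_s * fs) + 1):(n - round(trim_s * fs))
  list(phase = ph[keep], amp = am[keep])
}

#' Kullback-Leibler modulation index
#'
#' Quantifies coupling of a fast rhythm's amplitude to a slow rhythm's phase:
#' both bands are extracted with zero-phase band-pass filters, phase comes
#' from the analytic signal of the phase band and amplitude from the envelope
#' of the amplitude band; mean amplitude is binned by phase into `n_bins`
#' bins, normalized to a distribution `P`, and
#' `MI = KL(P || uniform) / log(n_bins)`, which lies in `[0, 1]` and is 0
#' exactly for a flat envelope.
#'
#' Multiple segments (e.g. the REM epochs of one animal) may be supplied;
#' phase and envelope are computed per segment and pooled into one phase-bin
#' histogram, so concatenation joins never enter the filters.
#'
#' @param x numeric vector, or list of numeric segments.
#' @param fs sampling rate, Hz.
#' @param phase_band,amp_band numeric `c(lo, hi)` in Hz.
#' @param n_bins number of phase bins (default 18).
#' @param trim_s seconds trimmed from each segment end after filtering.
#' @return scalar MI.
#' @export
modulation_index <- function(x, fs, phase_band, amp_band, n_bins = 18,
                             trim_s = 0.25) {
  segs <- if (is.list(x)) x else list(x)
  min_len <- 10 / phase_band[1] + 2 * trim_s
  if (any(lengths(segs) / fs < min_len)) {
    stop("input error: each segment must cover at least 10 cycles of the ",
         "phase band low edge plus trims")
  }
  amp_sum <- numeric(n_bins)
  amp_n <- numeric(n_bins)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  for (s in segs) {
    pa <- .phase_amp(s, fs, phase_band, amp_band, trim_s)
    bin <- findInterval(pa$phase, edges, rightmost.closed = TRUE)
    bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
    amp_sum <- amp_sum + vapply(seq_len(n_bins), function(b)
      sum(pa$amp[bin == b]), numeric(1))
    amp_n <- amp_n + tabulate(bin, n_bins)
  }
  m <- amp_sum / pmax(amp_n, 1)
  if (sum(m) == 0) return(0)
  P <- m / sum(m)
  P_pos <- P[P > 0]
  (log(n_bins) + sum(P_pos * log(P_pos))) / log(n_bins)
}

#' Phase-amplitude comodulogram
#'
#' Modulation index over a grid of (phase frequency, amplitude frequency)
#' cells.  Phase bands are `center +/- phase_bw/2`, amplitude bands
#' `center +/- amp_bw/2`.  Filtered phase/envelope series are cached per
#' band, so the cost is linear in the number of distinct bands, not cells.
#'
#' @param x numeric vector or list of segments.
#' @param fs sampling rate, Hz.
#' @param phase_centers,amp_centers grid centers in Hz (defaults 2-12 step 1
#'   and 20-120 step 5).
#' @param phase_bw,amp_bw band widths in Hz (defaults 2 and 20; the amplitude
#'   width accommodates the modulation sidebands of phase frequencies up to
#'   ~10 Hz).
#' @param n_bins phase bins for the MI.
#' @param channel,state optional labels.
#' @return object of class `sc_comodulogram`: `phase_freqs`, `amp_freqs`,
#'   matrix `mi` (phase x amplitude), labels.
#' @export
comodulogram <- function(x, fs, phase_centers = 2:12,
                         amp_centers = seq(20, 120, by = 5),
                         phase_bw = 2, amp_bw = 20, n_bins = 18,
                         channel = NA_character_, state = NA_character_) {
  segs <- if (is.list(x)) x else list(x)
  if (max(amp_centers) + amp_bw / 2 > fs / 2) {
    stop("input error: amplitude grid exceeds the Nyquist frequency")
  }
  trim_s <- 0.25
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  phase_bins <- lapply(phase_centers, function(fc) {
    lapply(segs, function(s) {
      ph <- Arg(analytic_signal(bp_filter(s, fs, fc - phase_bw / 2,
                                          fc + phase_bw / 2, trans_hz = 0.5)))
      keep <- (round(trim_s * fs) + 1):(length(s) - round(trim_s * fs))
      b <- findInterval(ph[keep], edges, rightmost.closed = TRUE)
      b[b < 1] <- 1; b[b > n_bins] <- n_bins
      b
    })
  })
  amp_envs <- lapply(amp_centers, function(fc) {
    lapply(segs, function(s) {
      am <- Mod(analytic_signal(bp_filter(s, fs, fc - amp_bw / 2, fc + amp_bw / 2)))
      keep <- (round(trim_s * fs) + 1):(length(s) - round(trim_s * fs))
      am[keep]
    })
  })
  mi <- matrix(0, length(phase_centers), length(amp_centers))
  for (i in seq_along(phase_centers)) {
    for (j in seq_along(amp_centers)) {
      amp_sum <- numeric(n_bins); amp_n <- numeric(n_bins)
      for (k in seq_along(segs)) {
        b <- phase_bins[[i]][[k]]
        a <- amp_envs[[j]][[k]]
        amp_sum <- amp_sum + vapply(seq_len(n_bins), function(bb)
          sum(a[b == bb]), numeric(1))
        amp_n <- amp_n + tabulate(b, n_bins)
      }
      m <- amp_sum / pmax(amp_n, 1)
      if (sum(m) > 0) {
        P <- m / sum(m); P <- P[P > 0]
        mi[i, j] <- (log(n_bins) + sum(P * log(P))) / log(n_bins)
      }
    }
  }
  structure(list(phase_freqs = phase_centers, amp_freqs = amp_centers, mi = mi,
                 channel = channel, state = state),
            class = "sc_comodulogram")
}

#' @export
print.sc_comodulogram <- function(x, ...) {
  am <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf("<comodulogram> %d x %d cells; max MI %.4g at phase %g Hz, amp %g Hz\n",
              nrow(x$mi), ncol(x$mi), max(x$mi),
              x$phase_freqs[am[1]], x$amp_freqs[am[2]]))
  invisible(x)
}

#' Mean modulation index over the high-coupling region
#'
#' Averages the comodulogram over cells whose centers fall in the
#' theta-gamma high-coupling region (phase 7-8 Hz, amplitude 60-90 Hz by
#' default), the per-animal summary compared between groups.
#'
#' @param c an `sc_comodulogram`.
#' @param phase_range,amp_range region bounds in Hz (inclusive of centers).
#' @return scalar mean MI.
#' @export
pac_summary <- function(c, phase_range = c(7, 8), amp_range = c(60, 90)) {
  stopifnot(inherits(c, "sc_comodulogram"))
  i <- which(c$phase_freqs >= phase_range[1] & c$phase_freqs <= phase_range[2])
  j <- which(c$amp_freqs >= amp_range[1] & c$amp_freqs <= amp_range[2])
  if (!length(i) || !length(j)) stop("input error: empty high-coupling region")
  mean(c$mi[i, j])
}

# REM segments of a recording as a list of numeric vectors (for PAC).
rem_segments <- function(r, h, channel, min_s = 10) {
  rl <- rle(h$labels)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  x <- chan(r, channel)
  segs <- list()
  for (i in which(rl$values == "REM" & rl$lengths * h$bin_s >= min_s)) {
    i0 <- round((starts[i] - 1L) * h$bin_s * r$fs) + 1L
    i1 <- min(round(ends[i] * h$bin_s * r$fs), length(x))
    segs[[length(segs) + 1]] <- x[i0:i1]
  }
  segs
}
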