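# Ripple-triggered cortical analyses: mean low-frequency mFC response and
# spindle-band power around ripples, normalized by inter-ripple baseline.

# Events usable for triggered analyses: NREM only, full window inside the
# recording, first `cap` in chronological order.
.usable_events <- function(events, duration_s, cap, window_s, states = "NREM") {
  ev <- events[events$state %in% states, , drop = FALSE]
  ev <- ev[ev$peak_s - window_s >= 0 & ev$peak_s + window_s <= duration_s, ,
           drop = FALSE]
  head(ev[order(ev$peak_s), , drop = FALSE], cap)
}

# Segment matrix (rows = lags, cols = events) of `x` around peak times.
.triggered_segments <- function(x, fs, peaks_s, window_s) {
  half <- round(window_s * fs)
  idx0 <- round(peaks_s * fs) + 1L
  vapply(idx0, function(i) x[(i - half):(i + half)], numeric(2 * half + 1))
}

#' Ripple-triggered average cortical response
#'
#' Averages the 1-50 Hz filtered mFC signal in windows centered on ripple
#' peaks.  Only NREM ripples are used; events whose window exceeds the
#' recording bounds are dropped; at most `cap` events (chronologically first)
#' enter the average.
#'
#' @param r a [recording()].
#' @param events ripple [event_table()] with a `state` column.
#' @param mfc_channel cortical channel (default `"mFC"`).
#' @param cap maximum number of events (default 585, so each animal
#'   contributes the same count).
#' @param window_s half-window in seconds (default 1: lags -1..+1 s).
#' @param band low-frequency band, Hz.
#' @return list of class `sc_triggered`: `lags_s`, `mean_trace` (uV),
#'   `n_events`.
#' @export
ripple_triggered_average <- function(r, events, mfc_channel = "mFC", cap = 585,
                                     window_s = 1, band = c(1, 50)) {
  ev <- .usable_events(events, r$duration_s, cap, window_s)
  if (!nrow(ev)) stop("no usable NREM ripple events")
  xf <- bp_filter(chan(r, mfc_channel), r$fs, band[1], band[2])
  seg <- .triggered_segments(xf, r$fs, ev$peak_s, window_s)
  structure(list(lags_s = seq(-window_s, window_s, by = 1 / r$fs),
                 mean_trace = rowMeans(seg), n_events = nrow(ev)),
            class = "sc_triggered")
}

#' Ripple-triggered normalized spindle power
#'
#' The mFC signal is band-passed to the spindle band (10-18 Hz); its
#' instantaneous power (squared envelope smoothed over `smooth_ms`) is
#' averaged across windows centered on ripple peaks, then divided by the
#' baseline power: the mean power over 2-s epochs centered at the midpoints
#' between consecutive used ripples.  For uncoupled data the normalized
#' power is ~1 at all lags.
#'
#' @inheritParams ripple_triggered_average
#' @param band spindle band, Hz.
#' @param smooth_ms power smoothing window (default 100 ms).
#' @param peak_lag_s the peak normalized power is the maximum over lags
#'   within `+/- peak_lag_s` of the ripple peak (default 0.5 s).
#' @param exclude_within_s optionally drop baseline midpoint epochs whose
#'   edges come within this many seconds of any used ripple peak; `NULL`
#'   (default) keeps every midpoint epoch, the plain midpoint rule.  At high
#'   event rates short inter-ripple gaps otherwise place baseline epochs
#'   inside the peri-event window.
#' @return list of class `sc_triggered_power`: `lags_s`, `norm_power`,
#'   `peak_norm_power`, `peak_lag_s` (location of the peak),
#'   `baseline_power` (uV^2), `n_events`.
#' @export
ripple_triggered_spindle_power <- function(r, events, mfc_channel = "mFC",
                                           cap = 585, window_s = 1,
                                           band = c(10, 18), smooth_ms = 100,
                                           peak_lag_s = 0.5,
                                           exclude_within_s = NULL) {
  ev <- .usable_events(events, r$duration_s, cap, window_s)
  if (nrow(ev) < 2) stop("need at least 2 usable events (midpoints required)")
  fs <- r$fs
  xf <- bp_filter(chan(r, mfc_channel), fs, band[1], band[2])
  pow <- smooth_ma(xf^2, max(1L, round(smooth_ms / 1000 * fs)))

  seg <- .triggered_segments(pow, fs, ev$peak_s, window_s)
  event_avg <- rowMeans(seg)

  baseline <- .interripple_power(pow, fs, ev$peak_s, r$duration_s,
                                 exclude_within_s = exclude_within_s)
  lags <- seq(-window_s, window_s, by = 1 / fs)
  norm_power <- event_avg / baseline
  in_peak <- abs(lags) <= peak_lag_s
  pk <- which.max(replace(norm_power, !in_peak, -Inf))
  structure(list(lags_s = lags, norm_power = norm_power,
                 peak_norm_power = norm_power[pk], peak_lag_s = lags[pk],
                 baseline_power = baseline, n_events = nrow(ev)),
            class = "sc_triggered_power")
}

# Mean power over 2-s epochs centered at midpoints between consecutive peaks.
# With `exclude_within_s`, midpoints whose epoch edge comes closer than that
# to any used peak are dropped (off by default: the plain midpoint rule).
.interripple_power <- function(pow, fs, peaks_s, duration_s, epoch_s = 2,
                               exclude_within_s = NULL) {
  mids <- (head(peaks_s, -1) + tail(peaks_s, -1)) / 2
  mids <- mids[mids - epoch_s / 2 >= 0 & mids + epoch_s / 2 <= duration_s]
  if (!is.null(exclude_within_s)) {
    gap <- vapply(mids, function(m) min(abs(peaks_s - m)), numeric(1))
    mids <- mids[gap - epoch_s / 2 >= exclude_within_s]
  }
  if (!length(mids)) stop("no valid inter-ripple epoch")
  half <- round(epoch_s / 2 * fs)
  vals <- vapply(round(mids * fs) + 1L, function(i) {
    mean(pow[(i - half):(i + half)])
  }, numeric(1))
  mean(vals)
}

#' Inter-ripple baseline spindle power
#'
#' The per-animal normalization constant of
#' [ripple_triggered_spindle_power()], reported on its own for the
#' between-genotype comparison of spindle power away from ripples.
#'
#' @inheritParams ripple_triggered_spindle_power
#' @return scalar mean spindle-band power (uV^2) over the 2-s midpoint
#'   epochs between consecutive used ripples.
#' @export
interripple_baseline_power <- function(r, events, mfc_channel = "mFC",
                                       cap = 585, window_s = 1,
                                       band = c(10, 18), smooth_ms = 100,
                                       exclude_within_s = NULL) {
  ev <- .usable_events(events, r$duration_s, cap, window_s)
  if (nrow(ev) < 2) stop("need at least 2 usable events (midpoints required)")
  fs <- r$fs
  xf <- bp_filter(chan(r, mfc_channel), fs, band[1], band[2])
  pow <- smooth_ma(xf^2, max(1L, round(smooth_ms / 1000 * fs)))
  .interripple_power(pow, fs, ev$peak_s, r$duration_s,
                     exclude_within_s = exclude_within_s)
}
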