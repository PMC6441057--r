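# CA1 sharp-wave-ripple detection and per-animal ripple metrics.

# Smoothed instantaneous ripple-band power: zero-phase band-pass, squared
# signal, centered moving average.  Shared by the detector and the synthetic
# generator's amplitude calibration.
ripple_power_envelope <- function(x, fs, band = c(150, 250), smooth_ms = 10) {
  xb <- bp_filter(x, fs, band[1], band[2])
  smooth_ma(xb^2, max(1L, round(smooth_ms / 1000 * fs)))
}

#' Ripple detector configuration
#'
#' @param band ripple band, Hz (default 150-250).
#' @param smooth_ms envelope smoothing window (default 10 ms).
#' @param low_sd candidate/boundary threshold in baseline SD units (default 2).
#' @param high_sd upper amplitude bound (default 5).
#' @param dur_ms accepted duration range in ms (default 50-100), applied
#'   after merging.
#' @param merge_gap_ms candidates closer than this are merged before the
#'   duration test (default 20 ms).
#' @param mode `"band"`: accept events whose peak z lies in
#'   `[low_sd, high_sd]` (the amplitude reading "from 2 to 5 SD above the
#'   baseline"); `"fma"`: boundaries at `low_sd`, peak must exceed `high_sd`
#'   (the FMAToolbox threshold-pair convention).
#' @param baseline_states hypnogram states whose samples define the
#'   z-scoring baseline (default NREM + WI; movement contaminates the ripple
#'   band).
#' @param keep_states detected events are retained only in these states.
#' @param spike_veto reject events dominated by spiking activity, an
#'   automatic stand-in for manual screening (spike transients are broadband,
#'   ripples are not): an event is vetoed when its high-frequency-band
#'   z-score at the peak exceeds `veto_ratio` times the ripple-band z, or
#'   when the median high-frequency z across the event exceeds
#'   `veto_median_z` (sustained broadband power, the signature of a merged
#'   spike burst rather than a ripple).
#' @param veto_ratio peak-ratio veto threshold (default 2).
#' @param veto_median_z sustained-broadband veto threshold in SD units
#'   (default 0.5).
#' @param veto_band high-frequency band for the veto, Hz; clipped to 95% of
#'   Nyquist, and the veto is skipped when the band collapses.
#' @return list of class `ripple_config`.
#' @export
ripple_config <- function(band = c(150, 250), smooth_ms = 10, low_sd = 2,
                          high_sd = 5, dur_ms = c(50, 100), merge_gap_ms = 20,
                          mode = c("band", "fma"),
                          baseline_states = c("NREM", "WI"),
                          keep_states = c("NREM", "WI"),
                          spike_veto = TRUE, veto_ratio = 2,
                          veto_median_z = 0.5, veto_band = c(500, 1000)) {
  structure(list(band = band, smooth_ms = smooth_ms, low_sd = low_sd,
                 high_sd = high_sd, dur_ms = dur_ms, merge_gap_ms = merge_gap_ms,
                 mode = match.arg(mode), baseline_states = baseline_states,
                 keep_states = keep_states, spike_veto = spike_veto,
                 veto_ratio = veto_ratio, veto_median_z = veto_median_z,
                 veto_band = veto_band),
            class = "ripple_config")
}

#' Detect sharp-wave ripples on a CA1 channel
#'
#' Pipeline: zero-phase band-pass (150-250 Hz); squared-signal envelope
#' smoothed over 10 ms; z-scored against the mean/SD over all NREM and WI
#' samples of the session; candidate events are contiguous regions above the
#' low threshold with boundaries at the threshold crossings; candidates
#' closer than the merge gap are merged; events must last 50-100 ms and have
#' a peak z inside the acceptance band (mode `"band"`) or above the high
#' threshold (mode `"fma"`).  The intraripple frequency is the median
#' instantaneous frequency (analytic-signal phase derivative) within the
#' event, and the state label comes from the hypnogram bin containing the
#' peak.
#'
#' @param r a [recording()].
#' @param h a [hypnogram()] covering the recording.
#' @param ca1_channel channel name or region (default `"CA1"`).
#' @param cfg a [ripple_config()].
#' @return an [event_table()] with `kind = "ripple"` and attribute columns
#'   `peak_z`, `intra_freq_hz`, `duration_ms`, `state`.
#' @export
detect_ripples <- function(r, h, ca1_channel = "CA1", cfg = ripple_config()) {
  stopifnot(inherits(r, "recording"), inherits(h, "hypnogram"))
  fs <- r$fs
  x <- chan(r, ca1_channel)
  st <- state_per_sample(h, length(x), fs)
  base <- st %in% cfg$baseline_states
  if (!any(base)) stop("no NREM/WI samples available for the baseline")

  env <- ripple_power_envelope(x, fs, cfg$band, cfg$smooth_ms)
  mu <- mean(env[base]); sdv <- sd(env[base])
  z <- (env - mu) / sdv

  above <- z > cfg$low_sd
  if (!any(above)) return(event_table())
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L

  # merge candidates separated by less than the merge gap
  gap_n <- round(cfg$merge_gap_ms / 1000 * fs)
  if (length(starts) > 1) {
    keep_start <- c(TRUE, (starts[-1] - ends[-length(ends)]) > gap_n)
    grp <- cumsum(keep_start)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }

  dur_ms <- (ends - starts + 1L) / fs * 1000
  peak_i <- mapply(function(s, e) s - 1L + which.max(z[s:e]), starts, ends)
  peak_z <- z[peak_i]

  ok <- dur_ms >= cfg$dur_ms[1] & dur_ms <= cfg$dur_ms[2]
  ok <- ok & if (cfg$mode == "band") {
    peak_z >= cfg$low_sd & peak_z <= cfg$high_sd
  } else {
    peak_z > cfg$high_sd
  }

  # spike-artifact veto: broadband high-frequency z must not dominate
  if (cfg$spike_veto && any(ok)) {
    v_hi <- min(cfg$veto_band[2], 0.95 * fs / 2)
    if (v_hi > cfg$veto_band[1] + 20) {
      venv <- ripple_power_envelope(x, fs, c(cfg$veto_band[1], v_hi), cfg$smooth_ms)
      vz <- (venv - mean(venv[base])) / sd(venv[base])
      med_vz <- mapply(function(s, e) median(vz[s:e]), starts, ends)
      ok <- ok & vz[peak_i] <= cfg$veto_ratio * peak_z &
        med_vz <= cfg$veto_median_z
    }
  }

  state <- st[peak_i]
  ok <- ok & state %in% cfg$keep_states
  if (!any(ok)) return(event_table())
  starts <- starts[ok]; ends <- ends[ok]; peak_i <- peak_i[ok]

  # intraripple frequency: median instantaneous frequency within the event
  xb <- bp_filter(x, fs, cfg$band[1], cfg$band[2])
  phase <- Arg(analytic_signal(xb))
  inst <- c(NA, diff(phase))
  inst <- ifelse(inst < -pi, inst + 2 * pi, ifelse(inst > pi, inst - 2 * pi, inst))
  inst_hz <- inst * fs / (2 * pi)
  intra <- mapply(function(s, e) median(inst_hz[s:e], na.rm = TRUE), starts, ends)

  event_table(start_s = (starts - 1L) / fs, peak_s = (peak_i - 1L) / fs,
              end_s = ends / fs, channel = rep(ca1_channel, length(starts)),
              kind = "ripple", peak_z = peak_z[ok],
              intra_freq_hz = intra, duration_ms = dur_ms[ok],
              state = state[ok])
}

#' Per-state ripple statistics
#'
#' @param events [event_table()] of detected ripples.
#' @param h the [hypnogram()] of the same recording.
#' @param states states to summarize (default NREM and WI).
#' @return data.frame `state`, `n`, `minutes`, `rate_per_min`,
#'   `mean_intra_freq_hz`, `mean_duration_ms`; a state with zero duration in
#'   the hypnogram yields an `NA` rate.
#' @export
ripple_stats <- function(events, h, states = c("NREM", "WI")) {
  out <- lapply(states, function(s) {
    mins <- sum(h$labels == s) * h$bin_s / 60
    ev <- events[events$state == s, , drop = FALSE]
    data.frame(state = s, n = nrow(ev), minutes = mins,
               rate_per_min = if (mins > 0) nrow(ev) / mins else NA_real_,
               mean_intra_freq_hz = if (nrow(ev)) mean(ev$intra_freq_hz) else NA_real_,
               mean_duration_ms = if (nrow(ev)) mean(ev$duration_ms) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching by peak-time proximity within a tolerance.
#'
#' @param detected,truth [event_table()]s.
#' @param tol_s maximum |peak time difference| for a match (default 25 ms).
#' @return list with counts `tp`, `fp`, `fn`, scalar `recall` and
#'   `precision`, and the matched index pairs.
#' @export
match_events <- function(detected, truth, tol_s = 0.025) {
  nd <- nrow(detected); nt <- nrow(truth)
  used <- logical(nt)
  pairs <- list()
  for (i in seq_len(nd)) {
    dt <- abs(truth$peak_s - detected$peak_s[i])
    dt[used] <- Inf
    j <- which.min(dt)
    if (nt && dt[j] <= tol_s) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(det = i, truth = j)
    }
  }
  tp <- length(pairs)
  list(tp = tp, fp = nd - tp, fn = nt - tp,
       recall = if (nt) tp / nt else NA_real_,
       precision = if (nd) tp / nd else NA_real_,
       pairs = if (tp) do.call(rbind, pairs) else matrix(numeric(), 0, 2))
}
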