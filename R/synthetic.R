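# Synthetic multichannel LFP/EEG/EMG generator with exact ground truth.
#
# The generator emulates the statistical structure the analysis chain relies
# on -- state-dependent spectral content, shared low-frequency background for
# nonzero interregional coherence, theta-phase-modulated gamma, CA1 ripples
# over a multi-unit spiking background, and a tunable ripple -> mFC spindle
# coupling -- not the biophysics of any particular circuit.

#' Default bout schedule (10-minute session)
#'
#' Movement, waking immobility, and two NREM->REM cycles with clean bouts of
#' at least 60 s, mirroring the alternation the staging rules assume.
#'
#' @param scale multiply every bout duration by this factor.
#' @return data.frame with columns `state`, `duration_s`.
#' @export
default_bout_schedule <- function(scale = 1) {
  data.frame(
    state = c("MOVE", "WI", "NREM", "REM", "NREM", "REM", "WI"),
    duration_s = scale * c(60, 90, 150, 60, 120, 60, 60),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the synthetic recording generator
#'
#' Defaults express the study conditions the analysis targets: 2 kHz
#' sampling, NREM rich in delta (2 Hz) with 10-18 Hz spindle activity, REM
#' carrying 7.5 Hz theta with 60-90 Hz gamma whose amplitude is modulated by
#' theta phase with depth `pac_strength`, CA1 ripples (160 Hz, 60 ms)
#' occurring in NREM and WI at 9/min over a pyramidal-layer spiking
#' background, and an optional ripple-triggered mFC spindle burst whose
#' amplitude scales with `coupling$gain`.
#'
#' @param seed integer master seed.
#' @param fs sampling rate, Hz.
#' @param bout_schedule data.frame of `state`, `duration_s` bouts.
#' @param channels channels to synthesize (subset of
#'   sFC, mFC, CA1, DG, RS, Th-RT, EMG).
#' @param noise list: `one_over_f_exponent`, `pink_sd_uv`, `shared_frac`
#'   (fraction of the pink background shared across neural channels),
#'   `white_sd_uv`.
#' @param nrem list: `delta_hz`, `delta_amp_uv`, `sigma_sd_uv` (continuous
#'   NREM sigma rhythm: a constant-envelope 10-15 Hz oscillation with slowly
#'   wandering frequency, so its band power is stationary), `spindle_hz`,
#'   `spindle_rate_per_min`, `spindle_dur_s`, `spindle_amp_uv`.
#' @param rem list: `theta_hz`, `theta_amp_uv`, `gamma_band`, `gamma_amp_uv`,
#'   `pac_strength` (kappa in `[0,1]`).
#' @param emg list: `move_burst_amp_uv`, `rest_amp_uv`.
#' @param ripples list: `rate_per_min`, `freq_hz`, `dur_ms`, `amp_sd`
#'   (detector z-score the injected peak is calibrated to), `refractory_s`,
#'   `taper` (fraction of the event under cosine ramps).  Under each event
#'   the ripple-band component of the background is crossfaded out, so the
#'   calibrated detector response of an injected event is well-defined.
#' @param spikes list: `rate_hz`, `amp_uv` -- multi-unit spiking background
#'   on the CA1 channel.  Spiking dominates the high-frequency baseline of a
#'   pyramidal-layer electrode; it is what the detector's spike veto (and the
#'   amplitude acceptance band) must contend with.
#' @param coupling list: `gain` (g >= 0; mFC spindle-burst amplitude in units
#'   of `nrem$spindle_amp_uv` placed at each ripple), `lag_ms`,
#'   `spindle_dur_s`.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(seed = 1L,
                         fs = 2000,
                         bout_schedule = default_bout_schedule(),
                         channels = c("sFC", "mFC", "CA1", "DG", "RS", "Th-RT", "EMG"),
                         noise = list(),
                         nrem = list(),
                         rem = list(),
                         emg = list(),
                         ripples = list(),
                         spikes = list(),
                         coupling = list()) {
  merge_defaults <- function(user, def) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  p <- list(
    seed = as.integer(seed),
    fs = fs,
    bout_schedule = bout_schedule,
    channels = channels,
    noise = merge_defaults(noise, list(one_over_f_exponent = 1, pink_sd_uv = 15,
                                       shared_frac = 0.6, white_sd_uv = 5)),
    nrem = merge_defaults(nrem, list(delta_hz = 2, delta_amp_uv = 60,
                                     sigma_sd_uv = 12, spindle_hz = 13,
                                     spindle_rate_per_min = 8, spindle_dur_s = 0.7,
                                     spindle_amp_uv = 30)),
    rem = merge_defaults(rem, list(theta_hz = 7.5, theta_amp_uv = 40,
                                   gamma_band = c(60, 90), gamma_amp_uv = 8,
                                   pac_strength = 0.8)),
    emg = merge_defaults(emg, list(move_burst_amp_uv = 80, rest_amp_uv = 8)),
    ripples = merge_defaults(ripples, list(rate_per_min = 9, freq_hz = 160,
                                           dur_ms = 60, amp_sd = 3,
                                           refractory_s = 0.25, taper = 0.2)),
    spikes = merge_defaults(spikes, list(rate_hz = 25, amp_uv = 60)),
    coupling = merge_defaults(coupling, list(gain = 0, lag_ms = 50,
                                             spindle_dur_s = 0.5))
  )
  stopifnot(p$fs > 0, nrow(p$bout_schedule) >= 1,
            all(p$bout_schedule$duration_s > 0),
            p$rem$pac_strength >= 0, p$rem$pac_strength <= 1,
            p$ripples$rate_per_min >= 0, p$coupling$gain >= 0)
  class(p) <- "synth_params"
  p
}

# Per-region gains of the shared/state components.
.GAINS <- list(
  delta  = c(sFC = 1, MC = 1, mFC = 1, RS = 0.8, `Th-RT` = 0.6, CA1 = 0.5, DG = 0.5),
  sigma  = c(sFC = 1, MC = 1, mFC = 1, RS = 0.8, `Th-RT` = 1),
  spindle = c(sFC = 1, MC = 1, mFC = 1, RS = 0.8, `Th-RT` = 1),
  theta  = c(CA1 = 1, DG = 1, sFC = 0.5, MC = 0.5, mFC = 0.5, RS = 0.3, `Th-RT` = 0.2),
  gamma  = c(CA1 = 0.8, DG = 1)
)

.gain <- function(component, region) {
  g <- .GAINS[[component]][region]
  ifelse(is.na(g), 0, unname(g))
}

# Add waveform w starting at sample i0 into vector x (clipped to bounds).
.add_at <- function(x, i0, w) {
  i1 <- i0 + length(w) - 1L
  j0 <- max(i0, 1L); j1 <- min(i1, length(x))
  if (j0 > j1) return(x)
  x[j0:j1] <- x[j0:j1] + w[(j0 - i0 + 1L):(j1 - i0 + 1L)]
  x
}

# Biphasic extracellular-spike template (derivative of a Gaussian), peak
# amplitude `amp`, width parameter sigma_s seconds.
.spike_template <- function(fs, amp, sigma_s = 4e-4) {
  t <- seq(-3 * sigma_s, 3 * sigma_s, by = 1 / fs)
  w <- -t * exp(-t^2 / (2 * sigma_s^2))
  amp * w / max(abs(w))
}

#' Generate a synthetic recording with ground truth
#'
#' @param p a [synth_params()].
#' @return a [recording()] whose `ground_truth` field holds the true
#'   [hypnogram()], an [event_table()] of injected ripples, spindles and
#'   coupled mFC bursts, and the generator parameters.  The injected ripple
#'   amplitude is calibrated against the recording's own baseline (including
#'   the spiking background) so that the detector's smoothed ripple-band
#'   z-score at the event peak is `ripples$amp_sd`.
#' @export
generate_recording <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  set.seed(p$seed)
  fs <- p$fs
  sched <- p$bout_schedule
  bout_end <- cumsum(sched$duration_s)
  bout_start <- c(0, head(bout_end, -1))
  total_s <- tail(bout_end, 1)
  n <- round(total_s * fs)
  tt <- (seq_len(n) - 1) / fs

  neural <- setdiff(p$channels, "EMG")
  chs <- stats::setNames(vector("list", length(p$channels)), p$channels)

  # background: shared pink + per-channel pink + white
  shared <- colored_noise(n, p$noise$one_over_f_exponent) * p$noise$pink_sd_uv
  own_sd <- p$noise$pink_sd_uv * sqrt(max(0, 1 - p$noise$shared_frac^2))
  for (ch in neural) {
    chs[[ch]] <- p$noise$shared_frac * shared +
      own_sd * colored_noise(n, p$noise$one_over_f_exponent) +
      p$noise$white_sd_uv * rnorm(n)
  }

  # multi-unit spiking background on CA1 (pyramidal layer)
  if ("CA1" %in% p$channels && p$spikes$rate_hz > 0) {
    tmpl <- .spike_template(fs, p$spikes$amp_uv)
    n_spk <- rpois(1, p$spikes$rate_hz * total_s)
    spk_i <- pmin(round(runif(n_spk, 0, total_s) * fs) + 1L, n)
    imp <- numeric(n)
    gains <- 0.5 + runif(n_spk)             # unit-to-unit amplitude spread
    for (k in seq_len(n_spk)) imp[spk_i[k]] <- imp[spk_i[k]] + gains[k]
    full <- fft_conv(imp, tmpl)
    c0 <- floor(length(tmpl) / 2)
    chs[["CA1"]] <- chs[["CA1"]] + full[(c0 + 1):(c0 + n)]
  }

  events <- list()
  ripple_times <- list()   # (start_s, state) before amplitude calibration

  for (b in seq_len(nrow(sched))) {
    st <- sched$state[b]
    i0 <- round(bout_start[b] * fs) + 1L
    i1 <- round(bout_end[b] * fs)
    idx <- i0:i1
    tb <- tt[idx]

    if (st == "NREM") {
      phase0 <- runif(1, 0, 2 * pi)
      delta <- p$nrem$delta_amp_uv * sin(2 * pi * p$nrem$delta_hz * tb + phase0)
      for (ch in neural) {
        g <- .gain("delta", ch)
        if (g > 0) chs[[ch]][idx] <- chs[[ch]][idx] + g * delta
        gs <- .gain("sigma", ch)
        if (gs > 0) {
          # constant-envelope sigma rhythm with a slowly wandering frequency:
          # oscillatory and narrowband like filtered noise, but with the
          # stationary band power a triggered average over hundreds of
          # events relies on (a Gaussian band noise has chi-squared power
          # fluctuations of CV ~ 1 instead)
          len <- length(idx)
          wander <- smooth_ma(rnorm(len), round(fs))
          wander <- wander / max(sd(wander), 1e-12)
          f_inst <- pmin(pmax(12.5 + 1.5 * wander, 10), 15)
          phi <- 2 * pi * cumsum(f_inst) / fs + runif(1, 0, 2 * pi)
          chs[[ch]][idx] <- chs[[ch]][idx] +
            gs * p$nrem$sigma_sd_uv * sqrt(2) * cos(phi)
        }
      }
      # discrete spindle bursts, shared across cortical/thalamic channels
      dur <- p$nrem$spindle_dur_s
      k <- rpois(1, p$nrem$spindle_rate_per_min * sched$duration_s[b] / 60)
      if (k > 0) {
        t0s <- sort(runif(k, bout_start[b], bout_end[b] - dur))
        for (t0 in t0s) {
          m <- round(dur * fs)
          w <- sin(2 * pi * p$nrem$spindle_hz * (seq_len(m) - 1) / fs +
                     runif(1, 0, 2 * pi)) * hamming_win(m)
          for (ch in neural) {
            g <- .gain("spindle", ch)
            if (g > 0) chs[[ch]] <- .add_at(chs[[ch]], round(t0 * fs) + 1L,
                                            g * p$nrem$spindle_amp_uv * w)
          }
          events[[length(events) + 1]] <- data.frame(
            start_s = t0, peak_s = t0 + dur / 2, end_s = t0 + dur,
            channel = "mFC", kind = "spindle", state = st, amp = NA_real_)
        }
      }
    } else if (st == "REM") {
      phase0 <- runif(1, 0, 2 * pi)
      theta_phase <- 2 * pi * p$rem$theta_hz * tb + phase0
      theta <- p$rem$theta_amp_uv * sin(theta_phase)
      for (ch in neural) {
        g <- .gain("theta", ch)
        if (g > 0) chs[[ch]][idx] <- chs[[ch]][idx] + g * theta
        gg <- .gain("gamma", ch)
        if (gg > 0) {
          gam <- band_noise(length(idx), fs, p$rem$gamma_band[1], p$rem$gamma_band[2])
          modul <- 1 + p$rem$pac_strength * cos(theta_phase)
          chs[[ch]][idx] <- chs[[ch]][idx] + gg * p$rem$gamma_amp_uv * gam * modul
        }
      }
    }

    # ripples occur during NREM and WI
    if (st %in% c("NREM", "WI") && "CA1" %in% p$channels &&
        p$ripples$rate_per_min > 0) {
      dur <- p$ripples$dur_ms / 1000
      t0 <- bout_start[b]
      repeat {
        t0 <- t0 + rexp(1, p$ripples$rate_per_min / 60) + p$ripples$refractory_s
        if (t0 + 2.2 * dur > bout_end[b]) break
        ripple_times[[length(ripple_times) + 1]] <- list(t0 = t0, state = st)
      }
    }
  }

  # EMG: rest noise everywhere, strong bursts in MOVE bouts
  if ("EMG" %in% p$channels) {
    e <- p$emg$rest_amp_uv * rnorm(n)
    for (b in which(sched$state == "MOVE")) {
      idx <- (round(bout_start[b] * fs) + 1L):round(bout_end[b] * fs)
      e[idx] <- p$emg$move_burst_amp_uv * rnorm(length(idx))
    }
    chs[["EMG"]] <- e
  }

  # true hypnogram (2-s bins, label at bin midpoint)
  bin_s <- 2
  nbins <- floor(total_s / bin_s)
  mid <- (seq_len(nbins) - 0.5) * bin_s
  true_labels <- sched$state[findInterval(mid, c(0, bout_end), rightmost.closed = TRUE)]
  truth <- hypnogram(true_labels, bin_s = bin_s)

  # Ripple injection.  The event replaces (crossfades out) the ripple-band
  # component of the background under its envelope, and the sinusoid
  # amplitude is calibrated so the detector's smoothed-power z-score at the
  # peak equals amp_sd.  `dur_ms` is the event's operational duration -- the
  # time its calibrated envelope spends above the detection threshold, the
  # same threshold-crossing definition the detector (and the field) uses for
  # ripple duration -- so the waveform support is solved to make the
  # over-threshold footprint equal dur_ms.  Ground-truth start/end are the
  # predicted crossings.
  if (length(ripple_times) && "CA1" %in% p$channels) {
    band <- c(150, 250)
    dur <- p$ripples$dur_ms / 1000
    env_bg <- ripple_power_envelope(chs[["CA1"]], fs, band, smooth_ms = 10)
    base_idx <- state_per_sample(truth, n, fs) %in% c("NREM", "WI")
    mu <- mean(env_bg[base_idx]); sdv <- sd(env_bg[base_idx])

    # solve for the support length whose above-threshold footprint is dur
    template_footprint <- function(L_s) {
      m <- round(L_s * fs)
      w_unit <- sin(2 * pi * p$ripples$freq_hz * (seq_len(m) - 1) / fs) *
        tukey_win(m, p$ripples$taper)
      probe <- numeric(max(round(fs), 2L * m))
      ctr <- round(length(probe) / 2)
      probe <- .add_at(probe, ctr - floor(m / 2), w_unit)
      e <- ripple_power_envelope(probe, fs, band, smooth_ms = 10)
      a2 <- (p$ripples$amp_sd * sdv + mu) / max(e)
      zt <- (a2 * e - mu) / sdv
      above <- which(zt > 2)
      list(m = m, w = w_unit, amp = sqrt(a2),
           width_s = length(above) / fs,
           lead_s = (ctr - floor(m / 2) - min(above)) / fs)
    }
    L <- dur / 0.55
    for (it in 1:8) {
      tf <- template_footprint(L)
      if (abs(tf$width_s - dur) < 5e-4) break
      L <- L * (1 + 0.8 * (dur / tf$width_s - 1))
    }
    m <- tf$m
    amp <- tf$amp
    in_band <- bp_filter(chs[["CA1"]], fs, band[1], band[2])
    taper_w <- tukey_win(m, p$ripples$taper)
    # in-band background is suppressed over the waveform support plus a
    # 30-ms guard on each side, so the event's threshold footprint is not
    # extended by adjacent background excursions
    pad <- round(0.03 * fs)
    msup <- m + 2L * pad
    supp <- tukey_win(msup, alpha = 2 * round(0.01 * fs) / msup)
    for (rp in ripple_times) {
      i0 <- round(rp$t0 * fs) + 1L
      if (i0 + m - 1L > n) next
      w <- amp * sin(2 * pi * p$ripples$freq_hz * (seq_len(m) - 1) / fs +
                       runif(1, 0, 2 * pi)) * taper_w
      s0 <- max(1L, i0 - pad)
      s1 <- min(n, i0 + m - 1L + pad)
      chs[["CA1"]][s0:s1] <- chs[["CA1"]][s0:s1] -
        supp[(s0 - (i0 - pad) + 1L):(s1 - (i0 - pad) + 1L)] * in_band[s0:s1]
      chs[["CA1"]] <- .add_at(chs[["CA1"]], i0, w)
      on_s <- rp$t0 - tf$lead_s           # predicted threshold crossing
      events[[length(events) + 1]] <- data.frame(
        start_s = on_s, peak_s = on_s + tf$width_s / 2, end_s = on_s + tf$width_s,
        channel = "CA1", kind = "ripple", state = rp$state, amp = amp)
      # ripple -> cortical spindle coupling
      if (p$coupling$gain > 0 && "mFC" %in% p$channels) {
        cs_dur <- p$coupling$spindle_dur_s
        cm <- round(cs_dur * fs)
        cw <- p$coupling$gain * p$nrem$spindle_amp_uv *
          sin(2 * pi * p$nrem$spindle_hz * (seq_len(cm) - 1) / fs) * hamming_win(cm)
        c0 <- rp$t0 + dur / 2 + p$coupling$lag_ms / 1000 - cs_dur / 2
        chs[["mFC"]] <- .add_at(chs[["mFC"]], round(c0 * fs) + 1L, cw)
        events[[length(events) + 1]] <- data.frame(
          start_s = c0, peak_s = c0 + cs_dur / 2, end_s = c0 + cs_dur,
          channel = "mFC", kind = "coupled_spindle", state = rp$state, amp = NA_real_)
      }
    }
  }

  ev <- if (length(events)) {
    validate_event_table(do.call(rbind, events))
  } else {
    event_table()
  }
  sig <- do.call(cbind, chs)
  colnames(sig) <- p$channels
  regions <- ifelse(p$channels %in% REGIONS, p$channels, "other")
  recording(sig, fs = fs, regions = regions,
            meta = list(synthetic = TRUE, seed = p$seed),
            ground_truth = list(hypnogram = truth, events = ev, params = p))
}

#' Generate a two-group synthetic cohort
#'
#' Emulates a transgenic-vs-wildtype design: `n_per_group[1]` animals from
#' `p_a` (group label `WT`) and `n_per_group[2]` from `p_b` (label `TG`),
#' with per-animal seeds derived deterministically from `seed`.
#'
#' @param p_a,p_b [synth_params()] for the two groups (the `seed` field is
#'   overridden per animal).
#' @param n_per_group integer vector `c(n_a, n_b)`, each at least 2.
#' @param seed master seed.
#' @param labels group labels, default `c("WT", "TG")`.
#' @return list of recordings; each carries `meta$animal` and `meta$genotype`.
#' @export
two_group_experiment <- function(p_a, p_b, n_per_group = c(6, 8), seed = 1L,
                                 labels = c("WT", "TG")) {
  stopifnot(all(n_per_group >= 2))
  out <- list()
  for (g in 1:2) {
    pg <- if (g == 1) p_a else p_b
    for (i in seq_len(n_per_group[g])) {
      pg$seed <- as.integer(seed + 1000L * (g - 1L) + i)
      r <- generate_recording(pg)
      r$meta$animal <- sprintf("%s%d", labels[g], i)
      r$meta$genotype <- labels[g]
      out[[length(out) + 1]] <- r
    }
  }
  out
}
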