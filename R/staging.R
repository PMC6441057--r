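# Rule-based sleep staging from 2-s bins of a cortical screw channel plus EMG,
# and selection of matched 20-s NREM/REM epoch pairs.

#' Staging band definitions
#'
#' Bands used by the bin classifier: delta and theta match the connectivity
#' bands; alpha and gamma (the NREM discriminant ratio) are set to 10-15 Hz
#' and 30-48 Hz, the gamma edge stopping below the 50 Hz line frequency.
#'
#' @return data.frame `name`, `lo_hz`, `hi_hz`.
#' @export
staging_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "gamma"),
             lo_hz = c(1, 5, 10, 30), hi_hz = c(4, 9, 15, 48),
             stringsAsFactors = FALSE)
}

#' Staging thresholds
#'
#' @param emg_k movement threshold in SD units: a bin is `MOVE` when its EMG
#'   envelope maximum exceeds `emg_k` times the standard deviation of the
#'   rectified EMG over the whole recording (default 2).
#' @param rem_factor a bin is `REM` when theta/delta exceeds `rem_factor`
#'   times the recording mean of that ratio (default 2).
#' @param rem_merge_factor relaxed theta/delta factor for merging a gap bin
#'   between two REM bins (default 1, i.e. still above the mean).
#' @param nrem_merge_factor relaxed alpha/gamma factor for merging a gap bin
#'   between two NREM bins (default 0.5, i.e. not below half the mean).
#' @param emg_threshold optional absolute EMG threshold in microvolts,
#'   overriding the SD rule (stands in for per-animal video adjustment).
#' @return list of class `staging_thresholds`.
#' @export
staging_thresholds <- function(emg_k = 2, rem_factor = 2, rem_merge_factor = 1,
                               nrem_merge_factor = 0.5, emg_threshold = NULL) {
  stopifnot(emg_k > 0, rem_factor > 0, rem_merge_factor > 0, nrem_merge_factor > 0)
  structure(list(emg_k = emg_k, rem_factor = rem_factor,
                 rem_merge_factor = rem_merge_factor,
                 nrem_merge_factor = nrem_merge_factor,
                 emg_threshold = emg_threshold),
            class = "staging_thresholds")
}

#' Per-bin staging features
#'
#' Divides the recording into `bin_s`-second bins and computes, per bin, the
#' maximum of a smoothed rectified-EMG envelope and the band powers of the
#' cortical screw channel from a short-time Fourier transform (1-s Hamming
#' windows, 50% overlap inside each bin), plus the two discriminant ratios
#' alpha/gamma (`r_ag`) and theta/delta (`r_td`).
#'
#' @param r a [recording()] with a screw channel and an EMG channel.
#' @param bin_s bin length in seconds (default 2); an incomplete trailing bin
#'   is dropped.
#' @param screw_channel,emg_channel channel names; default to the first
#'   channel of kind `screw` / `emg`.
#' @param bands band table as from [staging_bands()].
#' @return data.frame of class `bin_features` with one row per complete bin:
#'   `bin`, `start_s`, `emg_max`, `delta`, `theta`, `alpha`, `gamma`, `r_ag`,
#'   `r_td`; attribute `emg_sd` holds the SD of the rectified EMG.
#' @export
compute_bin_features <- function(r, bin_s = 2, screw_channel = NULL,
                                 emg_channel = NULL, bands = staging_bands()) {
  stopifnot(inherits(r, "recording"))
  if (is.null(screw_channel)) screw_channel <- chan_by_kind(r, "screw")
  if (is.null(emg_channel)) emg_channel <- chan_by_kind(r, "emg")
  if (is.null(screw_channel) || is.null(emg_channel)) {
    stop("configuration error: staging needs a cortical screw channel and an EMG channel")
  }
  fs <- r$fs
  eeg <- chan(r, screw_channel)
  emg <- chan(r, emg_channel)
  nbin <- floor(r$duration_s / bin_s)
  if (nbin < 1) stop("recording shorter than one bin")
  bin_n <- round(bin_s * fs)

  # EMG feature: max of a 50-ms moving-average rectified envelope per bin
  env <- smooth_ma(abs(emg), round(0.05 * fs))
  emg_max <- vapply(seq_len(nbin), function(k) {
    max(env[((k - 1) * bin_n + 1):(k * bin_n)])
  }, numeric(1))

  # STFT band powers: 1-s Hamming windows at 0.5-s hops, averaged within bin
  win_n <- round(1 * fs)
  hop_n <- round(0.5 * fs)
  w <- hamming_win(win_n)
  nkeep <- floor(win_n / 2) + 1
  freqs <- (seq_len(nkeep) - 1) * fs / win_n
  band_idx <- lapply(seq_len(nrow(bands)), function(i) {
    which(freqs >= bands$lo_hz[i] & freqs <= bands$hi_hz[i])
  })
  names(band_idx) <- bands$name
  pow <- matrix(NA_real_, nrow = nbin, ncol = nrow(bands),
                dimnames = list(NULL, bands$name))
  for (k in seq_len(nbin)) {
    starts <- seq((k - 1) * bin_n + 1, k * bin_n - win_n + 1, by = hop_n)
    segs <- vapply(starts, function(s) eeg[s:(s + win_n - 1)] * w, numeric(win_n))
    P <- rowMeans(Mod(stats::mvfft(matrix(segs, nrow = win_n)))^2)[seq_len(nkeep)]
    for (b in seq_along(band_idx)) pow[k, b] <- mean(P[band_idx[[b]]])
  }

  out <- data.frame(bin = seq_len(nbin), start_s = (seq_len(nbin) - 1) * bin_s,
                    emg_max = emg_max, pow,
                    r_ag = pow[, "alpha"] / pow[, "gamma"],
                    r_td = pow[, "theta"] / pow[, "delta"])
  attr(out, "emg_sd") <- sd(abs(emg))
  attr(out, "channels_used") <- c(screw_channel, emg_channel)
  class(out) <- c("bin_features", "data.frame")
  out
}

# One merge pass: relabel a single gap bin between two same-state neighbours
# when the relaxed ratio criterion holds and the animal is not moving.
.merge_pass <- function(lab, feat, state, ratio, thr) {
  n <- length(lab)
  if (n < 3) return(lab)
  for (i in 2:(n - 1)) {
    if (lab[i] != state && lab[i] != "MOVE" &&
        lab[i - 1] == state && lab[i + 1] == state &&
        is.finite(ratio[i]) && ratio[i] >= thr) {
      lab[i] <- state
    }
  }
  lab
}

#' Classify bins into sleep states
#'
#' Rule precedence per bin: movement (EMG envelope maximum above threshold)
#' wins; otherwise REM when theta/delta exceeds `rem_factor` times its
#' recording mean; otherwise NREM when alpha/gamma exceeds its recording
#' mean; all else waking immobility.  Two merging passes then relabel single
#' gap bins flanked by REM (NREM) bins whose ratio still satisfies the
#' relaxed threshold, iterated to a fixed point so the operation is
#' idempotent.
#'
#' @param f [compute_bin_features()] output.
#' @param th [staging_thresholds()].
#' @return a [hypnogram()].
#' @export
classify_bins <- function(f, th = staging_thresholds()) {
  stopifnot(inherits(f, "bin_features"), nrow(f) >= 1)
  emg_thr <- if (!is.null(th$emg_threshold)) th$emg_threshold else
    th$emg_k * attr(f, "emg_sd")
  mean_ag <- mean(f$r_ag[is.finite(f$r_ag)])
  mean_td <- mean(f$r_td[is.finite(f$r_td)])
  lab <- rep("WI", nrow(f))
  lab[is.finite(f$r_ag) & f$r_ag > mean_ag] <- "NREM"
  lab[is.finite(f$r_td) & f$r_td > th$rem_factor * mean_td] <- "REM"
  lab[f$emg_max > emg_thr] <- "MOVE"
  repeat {
    new <- .merge_pass(lab, f, "REM", f$r_td, th$rem_merge_factor * mean_td)
    new <- .merge_pass(new, f, "NREM", f$r_ag, th$nrem_merge_factor * mean_ag)
    if (identical(new, lab)) break
    lab <- new
  }
  hypnogram(lab, bin_s = f$start_s[2] - f$start_s[1],
            derived_from = attr(f, "channels_used"))
}

#' Stage a recording
#'
#' Convenience wrapper: [compute_bin_features()] then [classify_bins()].
#'
#' @inheritParams compute_bin_features
#' @param th [staging_thresholds()].
#' @return a [hypnogram()].
#' @export
stage_recording <- function(r, th = staging_thresholds(), bin_s = 2,
                            screw_channel = NULL, emg_channel = NULL) {
  classify_bins(compute_bin_features(r, bin_s, screw_channel, emg_channel), th)
}

#' Select matched 20-s NREM/REM epoch pairs
#'
#' For every REM bout of at least 10 bins: the REM segment is the bout's
#' first 10 bins; the 10 bins immediately before REM onset are excluded as
#' the transitional pre-REM gap (their labels are unconstrained); the NREM
#' segment is the 10 consecutive bins before that gap, required to be all
#' NREM.  Bouts failing any condition are dropped.
#'
#' @param h a [hypnogram()] with 2-s bins.
#' @return data.frame of class `epoch_pairs` with one row per retained REM
#'   bout: `nrem_start_s`, `rem_start_s` (each segment lasts 20 s).
#' @export
select_epoch_pairs <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  nb <- 10L  # bins per segment
  lab <- h$labels
  rl <- rle(lab)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  out <- list()
  for (i in which(rl$values == "REM")) {
    if (rl$lengths[i] < nb) next
    s <- starts[i]
    nrem_first <- s - 2L * nb
    if (nrem_first < 1) next
    if (!all(lab[nrem_first:(s - nb - 1L)] == "NREM")) next
    out[[length(out) + 1]] <- data.frame(
      nrem_start_s = (nrem_first - 1L) * h$bin_s,
      rem_start_s = (s - 1L) * h$bin_s)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(nrem_start_s = numeric(), rem_start_s = numeric())
  attr(res, "segment_s") <- nb * h$bin_s
  class(res) <- c("epoch_pairs", "data.frame")
  res
}

#' Staging accuracy against a reference hypnogram
#'
#' @param h,truth [hypnogram()]s of equal length and bin size.
#' @return list with `confusion` (rows = true state, columns = predicted),
#'   `accuracy` (overall fraction correct) and `per_state` accuracy.
#' @export
staging_accuracy <- function(h, truth) {
  if (length(h$labels) != length(truth$labels) || h$bin_s != truth$bin_s) {
    stop("integrity error: hypnograms differ in length or bin size")
  }
  cm <- table(factor(truth$labels, levels = STATES),
              factor(h$labels, levels = STATES))
  per_state <- diag(cm) / rowSums(cm)
  list(confusion = cm,
       accuracy = sum(diag(cm)) / sum(cm),
       per_state = per_state)
}

#' REM bout recall
#'
#' Fraction of true REM bouts (of at least `min_bins` bins) in which at least
#' `min_frac` of the bins are labelled REM by the prediction.
#'
#' @param h predicted [hypnogram()]; `truth` the reference.
#' @param min_frac required fraction of correctly labelled bins per bout.
#' @param min_bins minimum true bout length in bins to count as a bout.
#' @return scalar recall in `[0, 1]` (`NA` when truth has no qualifying bout).
#' @export
rem_bout_recall <- function(h, truth, min_frac = 0.5, min_bins = 5L) {
  rl <- rle(truth$labels)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  bouts <- which(rl$values == "REM" & rl$lengths >= min_bins)
  if (!length(bouts)) return(NA_real_)
  hit <- vapply(bouts, function(i) {
    mean(h$labels[starts[i]:ends[i]] == "REM") >= min_frac
  }, logical(1))
  mean(hit)
}
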