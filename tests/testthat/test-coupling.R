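# A stationary-noise recording with regularly spaced pseudo-events lets the
# coupling operations be tested against arithmetic expectations.
noise_recording_with_events <- function(n_events = 100, gap_s = 3, fs = 500,
                                        seed = 71, amp = 1) {
  set.seed(seed)
  dur <- (n_events + 1) * gap_s
  sig <- matrix(rnorm(dur * fs * 2, sd = amp), ncol = 2)
  colnames(sig) <- c("CA1", "mFC")
  r <- recording(sig, fs = fs)
  peaks <- seq_len(n_events) * gap_s
  ev <- event_table(start_s = peaks - 0.03, peak_s = peaks, end_s = peaks + 0.03,
                    channel = "CA1", kind = "ripple", state = "NREM")
  list(r = r, ev = ev)
}

test_that("triggered average recovers an identical injected transient", {
  fs <- 500
  x <- noise_recording_with_events(n_events = 80, fs = fs, amp = 0.3)
  r <- x$r
  tt <- seq(-0.25, 0.25, by = 1 / fs)
  transient <- 20 * cos(2 * pi * 10 * tt) * exp(-tt^2 / (2 * 0.05^2))
  for (pk in x$ev$peak_s) {
    i <- round(pk * fs) + 1
    idx <- (i - 125):(i + 125)
    r$signals[idx, "mFC"] <- r$signals[idx, "mFC"] + transient
  }
  ta <- ripple_triggered_average(r, x$ev, window_s = 1)
  expect_equal(ta$n_events, 80)
  i0 <- which(ta$lags_s == 0)
  expect_equal(ta$mean_trace[i0], max(transient), tolerance = 0.05 * max(transient))
  # noise suppressed roughly as 1/sqrt(n)
  edge <- abs(ta$lags_s) > 0.6
  expect_lt(sd(ta$mean_trace[edge]), 3 * 0.3 / sqrt(80))
})

test_that("triggered average honours the event cap and NREM-only rule", {
  x <- noise_recording_with_events(n_events = 100)
  ev <- x$ev
  ev$state[1:10] <- "WI"
  ta <- ripple_triggered_average(x$r, ev, cap = 50)
  expect_equal(ta$n_events, 50)
  # chronological first-n of the NREM events: peaks 11..60
  ta2 <- ripple_triggered_average(x$r, ev, cap = 1000)
  expect_equal(ta2$n_events, 90)
  expect_error(ripple_triggered_average(x$r, ev[0, ]), "usable")
})

test_that("normalized spindle power is ~1 for stationary noise and flags real coupling", {
  x <- noise_recording_with_events(n_events = 100, seed = 72)
  tp <- ripple_triggered_spindle_power(x$r, x$ev)
  expect_equal(tp$peak_norm_power, 1, tolerance = 0.25)
  expect_equal(mean(tp$norm_power), 1, tolerance = 0.1)

  # generator with strong coupling: peak >> 1, near lag 0 (+ configured lag)
  p <- synth_params(seed = 73, fs = 1000,
                    bout_schedule = data.frame(state = "NREM", duration_s = 180),
                    channels = c("CA1", "mFC"),
                    ripples = list(rate_per_min = 15),
                    coupling = list(gain = 2))
  r <- generate_recording(p)
  ev <- detect_ripples(r, r$ground_truth$hypnogram)
  tp2 <- ripple_triggered_spindle_power(r, ev, cap = 40, exclude_within_s = 1)
  expect_gt(tp2$peak_norm_power, 1.5)
  expect_lt(abs(tp2$peak_lag_s), 0.1)
})

test_that("a +100 ms configured lag shifts the power peak accordingly", {
  p <- synth_params(seed = 74, fs = 1000,
                    bout_schedule = data.frame(state = "NREM", duration_s = 180),
                    channels = c("CA1", "mFC"),
                    ripples = list(rate_per_min = 15),
                    coupling = list(gain = 2, lag_ms = 150))
  r <- generate_recording(p)
  ev <- detect_ripples(r, r$ground_truth$hypnogram)
  tp <- ripple_triggered_spindle_power(r, ev, cap = 40, exclude_within_s = 1)
  expect_equal(tp$peak_lag_s, 0.15, tolerance = 0.1)  # within a smoothing window
})

test_that("inter-ripple baseline matches constant power and identical inputs", {
  fs <- 500
  n <- 300 * fs
  tt <- (seq_len(n) - 1) / fs
  sig <- cbind(CA1 = rnorm(n), mFC = 10 * sin(2 * pi * 13 * tt))
  r <- recording(sig, fs = fs)
  peaks <- seq(5, 295, by = 3)
  ev <- event_table(start_s = peaks - 0.03, peak_s = peaks, end_s = peaks + 0.03,
                    channel = "CA1", kind = "ripple", state = "NREM")
  b <- interripple_baseline_power(r, ev)
  expect_equal(b, 50, tolerance = 0.02 * 50)  # A^2/2 for A = 10

  x <- noise_recording_with_events(seed = 75)
  b1 <- interripple_baseline_power(x$r, x$ev)
  r2 <- x$r; r2$meta$animal <- "copy"
  expect_identical(interripple_baseline_power(r2, x$ev), b1)
  expect_error(interripple_baseline_power(x$r, x$ev[1, ]), "at least 2")
})

test_that("using baseline epochs as events gives normalized power ~1 everywhere", {
  x <- noise_recording_with_events(n_events = 99, seed = 76)
  mids <- (head(x$ev$peak_s, -1) + tail(x$ev$peak_s, -1)) / 2
  ev_mid <- event_table(start_s = mids - 0.03, peak_s = mids, end_s = mids + 0.03,
                        channel = "CA1", kind = "ripple", state = "NREM")
  tp <- ripple_triggered_spindle_power(x$r, ev_mid)
  expect_lt(max(abs(tp$norm_power - 1)), 0.35)
  expect_equal(mean(tp$norm_power), 1, tolerance = 0.05)
})
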