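# Helper: build a bin_features table by hand (bypassing the STFT) so the
# classification rules can be tested against exact inputs.
make_features <- function(emg_max, r_ag, r_td, emg_sd = 1, bin_s = 2) {
  n <- max(length(emg_max), length(r_ag), length(r_td))
  f <- data.frame(bin = seq_len(n), start_s = (seq_len(n) - 1) * bin_s,
                  emg_max = rep_len(emg_max, n),
                  delta = 1, theta = rep_len(r_td, n),
                  alpha = rep_len(r_ag, n), gamma = 1,
                  r_ag = rep_len(r_ag, n), r_td = rep_len(r_td, n))
  attr(f, "emg_sd") <- emg_sd
  attr(f, "channels_used") <- c("sFC", "EMG")
  class(f) <- c("bin_features", "data.frame")
  f
}

test_that("bin features: bin count, spectral content and EMG behave as constructed", {
  fs <- 400
  n <- round(61 * fs)
  sig <- cbind(sFC = sin(2 * pi * 7.5 * (seq_len(n) - 1) / fs), EMG = rep(0, n))
  r <- recording(sig, fs = fs)
  f <- compute_bin_features(r)
  expect_equal(nrow(f), 30)  # floor(61 / 2), trailing partial bin dropped
  expect_true(all(f$theta > 10 * f$delta))
  expect_true(all(f$emg_max == 0))

  no_emg <- recording(sig[, 1, drop = FALSE], fs = fs)
  expect_error(compute_bin_features(no_emg), "configuration error")
})

test_that("classification applies movement > REM > NREM > WI with recording-mean references", {
  # mean r_ag = 1.0 and mean r_td = 7/6 by construction
  f <- make_features(
    emg_max = c(5, 0, 0, 0, 0, 0),
    r_ag   = c(1, 2.0, 0.5, 1.0, 0.8, 0.7),
    r_td   = c(3, 2.5, 0.5, 0.5, 0.25, 0.25),
    emg_sd = 1)
  h <- classify_bins(f, staging_thresholds(emg_k = 2))
  # bin 1: EMG wins despite REM-level theta/delta
  expect_equal(h$labels[1], "MOVE")
  # bin 2: r_td 2.5 > 2 x mean wins over the NREM criterion (r_ag 2 > mean)
  expect_equal(h$labels[2], "REM")
  # bin 4: neither ratio above threshold -> WI
  expect_equal(h$labels[4], "WI")
})

test_that("degenerate all-identical features below thresholds give all WI", {
  f <- make_features(emg_max = rep(0.5, 8), r_ag = rep(1, 8), r_td = rep(1, 8),
                     emg_sd = 1)
  h <- classify_bins(f)
  expect_true(all(h$labels == "WI"))
})

test_that("REM and NREM merge rules relabel qualifying gap bins and are idempotent", {
  # REM, gap (r_td = 1.5 x mean, no movement), REM  -> gap becomes REM
  r_td <- c(0.1, 2.2, 1.3, 2.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  # mean r_td = 0.74 -> REM needs > 1.48; gap bin 1.3 > 0.74 merges
  f <- make_features(emg_max = 0, r_ag = 0.5, r_td = r_td, emg_sd = 1)
  h <- classify_bins(f)
  expect_equal(h$labels[2:4], c("REM", "REM", "REM"))

  # moving gap bin is never merged
  f2 <- make_features(emg_max = c(0, 0, 5, 0, 0), r_ag = 0.5,
                      r_td = c(2.2, 2.2, 1.3, 2.2, 0.1), emg_sd = 1)
  h2 <- classify_bins(f2, staging_thresholds(emg_k = 2))
  expect_equal(h2$labels[3], "MOVE")

  # applying the merge passes to a classified hypnogram changes nothing
  lab <- h$labels
  mean_td <- mean(f$r_td)
  relab <- sleepcouple:::.merge_pass(lab, f, "REM", f$r_td, mean_td)
  expect_identical(relab, lab)
})

test_that("epoch-pair selection takes 10 REM bins, skips a 10-bin gap, needs 10 NREM bins", {
  lab <- c(rep("WI", 5), rep("NREM", 20), rep("WI", 10), rep("REM", 12), rep("WI", 5))
  # gap = bins 26..35 (here WI) and NREM segment = bins 16..25: gap content free
  h <- hypnogram(lab, bin_s = 2)
  ep <- select_epoch_pairs(h)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$rem_start_s, 35 * 2)
  expect_equal(ep$nrem_start_s, 15 * 2)

  # REM bout of 8 bins: no pair
  lab2 <- c(rep("NREM", 20), rep("NREM", 10), rep("REM", 8), rep("WI", 4))
  expect_equal(nrow(select_epoch_pairs(hypnogram(lab2))), 0)

  # a MOVE bin inside the gap does not prevent the pair
  lab3 <- c(rep("NREM", 20), rep("NREM", 5), "MOVE", rep("NREM", 4), rep("REM", 10))
  expect_equal(nrow(select_epoch_pairs(hypnogram(lab3))), 1)

  # non-NREM bin inside the pre-gap NREM segment drops the bout
  lab4 <- c(rep("NREM", 15), "WI", rep("NREM", 4), rep("NREM", 10), rep("REM", 10))
  expect_equal(nrow(select_epoch_pairs(hypnogram(lab4))), 0)
})

test_that("staging accuracy and REM bout recall summarize agreement correctly", {
  truth <- hypnogram(rep(c("WI", "NREM", "REM", "MOVE"), each = 5))
  expect_equal(staging_accuracy(truth, truth)$accuracy, 1)
  allwi <- hypnogram(rep("WI", 20))
  acc <- staging_accuracy(allwi, truth)
  expect_equal(acc$accuracy, 0.25)
  expect_equal(unname(acc$per_state["WI"]), 1)
  expect_equal(sum(acc$confusion), 20)
  expect_error(staging_accuracy(hypnogram(rep("WI", 3)), truth), "integrity")

  set.seed(8)
  rnd <- hypnogram(sample(c("WI", "NREM", "REM", "MOVE"), 4000, replace = TRUE))
  rtruth <- hypnogram(rep(c("WI", "NREM", "REM", "MOVE"), 1000))
  expect_equal(staging_accuracy(rnd, rtruth)$accuracy, 0.25, tolerance = 0.1)

  expect_equal(rem_bout_recall(truth, truth), 1)
  expect_equal(rem_bout_recall(allwi, truth), 0)
})

test_that("classification is invariant to joint signal/threshold rescaling and channel order", {
  r <- default_animal(2)
  f <- compute_bin_features(r)
  base_thr <- 2 * attr(f, "emg_sd")
  h1 <- classify_bins(f, staging_thresholds(emg_threshold = base_thr))

  r2 <- r
  r2$signals <- r$signals * 2
  f2 <- compute_bin_features(r2)
  h2 <- classify_bins(f2, staging_thresholds(emg_threshold = 2 * base_thr))
  expect_identical(h1$labels, h2$labels)

  r3 <- r
  perm <- rev(seq_len(ncol(r$signals)))
  r3$signals <- r$signals[, perm]
  r3$channels <- r$channels[perm, ]
  h3 <- stage_recording(r3)
  expect_identical(stage_recording(r)$labels, h3$labels)
})

test_that("staging recovers clean synthetic state structure", {
  r <- default_animal(1)
  h <- stage_recording(r)
  acc <- staging_accuracy(h, r$ground_truth$hypnogram)
  expect_gte(acc$accuracy, 0.90)
  expect_gte(rem_bout_recall(h, r$ground_truth$hypnogram), 0.95)
})
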