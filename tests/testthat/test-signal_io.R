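test_that("recording constructor enforces its invariants", {
  r <- toy_recording()
  expect_s3_class(r, "recording")
  expect_equal(r$duration_s, nrow(r$signals) / r$fs)
  expect_equal(r$channels$kind, c("screw", "wire", "emg"))

  expect_error(recording(list(a = 1:10, b = 1:5), fs = 10), "unequal")
  sig <- matrix(0, 10, 2); colnames(sig) <- c("x", "x")
  expect_error(recording(sig, fs = 10), "unique")
  sig2 <- matrix(0, 10, 1); colnames(sig2) <- "e"
  expect_error(recording(sig2, fs = 10, regions = "EMG", kinds = "wire"),
               "EMG if and only if")
  expect_error(recording(sig2, fs = -1), "fs")
})

test_that("slicing respects bounds, preserves duration, and concatenates losslessly", {
  r <- toy_recording(duration_s = 10, fs = 200)
  expect_equal(slice_recording(r, 0, r$duration_s)$signals, r$signals)

  s <- slice_recording(r, 1, 3)
  expect_equal(nrow(s$signals), 2 * r$fs)
  expect_equal(s$meta$animal, "toy")

  expect_error(slice_recording(r, 10, 5), "bounds")
  expect_error(slice_recording(r, -1, 5), "bounds")
  expect_error(slice_recording(r, 0, 2, channels = "nope"), "unknown channel")

  # slicing then concatenating adjacent slices reproduces the signal exactly
  for (cut in c(0.5, 3.1415, 7)) {
    a <- slice_recording(r, 0, cut)
    b <- slice_recording(r, cut, r$duration_s)
    expect_identical(rbind(a$signals, b$signals), r$signals)
  }
})

test_that("a 20-s slice at 2 kHz has 40000 samples", {
  sig <- matrix(0, 60 * 2000, 1); colnames(sig) <- "CA1"
  r <- recording(sig, fs = 2000)
  expect_equal(nrow(slice_recording(r, 10, 30)$signals), 40000)
})

test_that("container round-trip is lossless, including ground truth", {
  skip_if_not_installed("jsonlite")
  for (seed in c(5, 6)) {
    set.seed(seed)
    r <- quantize32(toy_recording(duration_s = 2, fs = 100, seed = seed))
    r$ground_truth <- list(
      hypnogram = hypnogram(c("WI", "NREM"), bin_s = 1),
      events = event_table(0.1, 0.15, 0.2, "CA1", "ripple", peak_z = 3.25),
      params = list(seed = seed))
    path <- withr::local_tempfile(fileext = ".rec")
    write_recording(r, path)
    r2 <- read_recording(path, "container")
    expect_identical(r2$signals, r$signals)
    expect_equal(r2$fs, r$fs)
    expect_equal(r2$channels, r$channels)
    expect_equal(r2$ground_truth$hypnogram$labels, c("WI", "NREM"))
    expect_equal(r2$ground_truth$events$peak_z, 3.25)
    # second round trip is bit-stable
    path2 <- withr::local_tempfile(fileext = ".rec")
    write_recording(r2, path2)
    expect_identical(readBin(path, "raw", file.size(path)),
                     readBin(path2, "raw", file.size(path2)))
  }
  expect_error(read_recording(withr::local_tempfile(lines = "not a container")),
               "magic")
})

test_that("EDF reading maps signals and rejects mixed sampling rates", {
  set.seed(3)
  n <- 400
  sig <- matrix(round(rnorm(n * 3), 1) * 10, n, 3)
  colnames(sig) <- c("mFC", "CA1", "EMG1")
  path <- withr::local_tempfile(fileext = ".edf")
  write_test_edf(path, sig, fs = 200)
  r <- read_recording(path, "edf")
  expect_equal(ncol(r$signals), 3)
  expect_equal(r$fs, 200)
  expect_equal(r$channels$region, c("mFC", "CA1", "EMG"))
  expect_lt(max(abs(r$signals - sig)), 0.11)  # 16-bit quantization step

  path2 <- withr::local_tempfile(fileext = ".edf")
  write_test_edf(path2, sig, fs = 200, samples_per_record = c(200, 200, 100))
  expect_error(read_recording(path2, "edf"), "sampling rates differ")
})

test_that("event tables round-trip through CSV and reject inverted intervals", {
  t_empty <- event_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(t_empty, path)
  expect_equal(nrow(read_events(path)), 0)

  t3 <- event_table(start_s = c(2.5, 0.1, 1.0), peak_s = c(2.53, 0.15, 1.02),
                    end_s = c(2.56, 0.2, 1.06), channel = "CA1", kind = "ripple",
                    peak_z = c(3.1, 2.9, 4.2))
  expect_equal(t3$start_s, c(0.1, 1.0, 2.5))  # sorted on construction
  write_events(t3, path)
  t3b <- read_events(path)
  expect_equal(as.data.frame(t3b), as.data.frame(t3), tolerance = 1e-9)
  # byte-stable on rewrite
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_events(t3b, path2)
  expect_identical(readLines(path), readLines(path2))

  expect_error(event_table(1, 1.5, 1.2, "CA1", "ripple"), "integrity")
})

test_that("hypnograms round-trip through CSV", {
  h <- hypnogram(c("WI", "NREM", "NREM", "REM", "MOVE"), bin_s = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(h, path)
  h2 <- read_hypnogram(path)
  expect_equal(h2$labels, h$labels)
  expect_equal(h2$bin_s, 2)
  expect_error(hypnogram(c("NREM", "AWAKE")), "unknown state")
})
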