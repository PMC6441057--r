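test_that("modulation index is near zero for white noise and zero for a flat envelope", {
  set.seed(51)
  expect_lt(modulation_index(rnorm(120000), 2000, c(6.5, 8.5), c(60, 90)), 0.01)

  # unmodulated tone in the amplitude band: envelope flat, MI ~ 0
  fs <- 1000
  tt <- (0:(60 * fs - 1)) / fs
  x <- cos(2 * pi * 8 * tt) + cos(2 * pi * 75 * tt)
  expect_lt(modulation_index(x, fs, c(7, 9), c(65, 85)), 1e-4)

  expect_error(modulation_index(rnorm(1000), 2000, c(6, 8), c(60, 90)), "10 cycles")
})

test_that("modulation index matches a closed-form phase-binned oracle", {
  fs <- 1000
  tt <- (0:(120 * fs - 1)) / fs
  phase <- 2 * pi * 8 * tt
  x <- cos(phase) + (1 + 0.5 * cos(phase)) * cos(2 * pi * 75 * tt)
  mi <- modulation_index(x, fs, c(7, 9), c(65, 85), n_bins = 18)
  # oracle: mean amplitude per phase bin computed analytically from
  # A(phi) = 1 + 0.5 cos(phi), then the same KL/log(n) definition
  n <- 18
  edges <- seq(-pi, pi, length.out = n + 1)
  m <- vapply(seq_len(n), function(j) {
    integrate(function(p) 1 + 0.5 * cos(p), edges[j], edges[j + 1])$value
  }, numeric(1))
  P <- m / sum(m)
  mi_oracle <- (log(n) + sum(P * log(P))) / log(n)
  expect_equal(mi, mi_oracle, tolerance = 0.05 * mi_oracle + 1e-4)
})

test_that("modulation index is invariant to amplitude scaling", {
  p <- synth_params(seed = 52, bout_schedule = data.frame(state = "REM", duration_s = 60),
                    channels = "DG")
  x <- generate_recording(p)$signals[, "DG"]
  m1 <- modulation_index(x, 2000, c(6.5, 8.5), c(60, 90))
  m2 <- modulation_index(13 * x, 2000, c(6.5, 8.5), c(60, 90))
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("coupled synthetic REM yields MI far above noise, destroyed by phase scrambling", {
  p <- synth_params(seed = 53, bout_schedule = data.frame(state = "REM", duration_s = 60),
                    channels = "DG", rem = list(pac_strength = 0.8))
  x <- generate_recording(p)$signals[, "DG"]
  fs <- 2000
  mi <- modulation_index(x, fs, c(6.5, 8.5), c(60, 90))
  set.seed(53)
  mi_noise <- modulation_index(rnorm(length(x), sd = sd(x)), fs, c(6.5, 8.5), c(60, 90))
  expect_gt(mi, 10 * mi_noise)

  # FFT phase randomization preserves the spectrum but kills the coupling
  set.seed(54)
  X <- fft(x)
  nf <- length(x)
  ph <- runif(nf, 0, 2 * pi)
  if (nf %% 2 == 0) {
    half <- 2:(nf / 2)
    ph[1] <- 0; ph[nf / 2 + 1] <- 0
  } else {
    half <- 2:((nf + 1) / 2)
    ph[1] <- 0
  }
  ph[nf + 2 - half] <- -ph[half]
  xs <- Re(fft(Mod(X) * exp(1i * ph), inverse = TRUE) / nf)
  mi_surr <- modulation_index(xs, fs, c(6.5, 8.5), c(60, 90))
  expect_lt(mi_surr, 0.1 * mi)
})

test_that("MI pools multiple segments into one phase histogram", {
  p <- synth_params(seed = 55, bout_schedule = data.frame(state = "REM", duration_s = 60),
                    channels = "DG")
  x <- generate_recording(p)$signals[, "DG"]
  whole <- modulation_index(x, 2000, c(6.5, 8.5), c(60, 90))
  halves <- modulation_index(list(x[1:60000], x[60001:120000]), 2000,
                             c(6.5, 8.5), c(60, 90))
  expect_equal(halves, whole, tolerance = 0.05)
})

test_that("comodulogram peaks in the generator's coupling region and matches single cells", {
  p <- synth_params(seed = 56, bout_schedule = data.frame(state = "REM", duration_s = 120),
                    channels = "DG")
  r <- generate_recording(p)
  x <- r$signals[, "DG"]
  cm <- comodulogram(x, r$fs)
  am <- arrayInd(which.max(cm$mi), dim(cm$mi))
  expect_true(cm$phase_freqs[am[1]] %in% 7:8)
  expect_gte(cm$amp_freqs[am[2]], 60)
  expect_lte(cm$amp_freqs[am[2]], 90)

  # a one-cell grid equals modulation_index on that band pair
  one <- comodulogram(x, r$fs, phase_centers = 8, amp_centers = 75)
  direct <- modulation_index(x, r$fs, c(7, 9), c(65, 85))
  expect_equal(one$mi[1, 1], direct, tolerance = 1e-10)

  expect_error(comodulogram(x, r$fs, amp_centers = 1100), "Nyquist")
})

test_that("the region summary averages the right cells and grows with coupling", {
  cm <- structure(list(phase_freqs = 2:12, amp_freqs = seq(20, 120, 5),
                       mi = matrix(0.25, 11, 21)),
                  class = "sc_comodulogram")
  expect_equal(pac_summary(cm), 0.25)
  cm$mi[6, 10] <- 0.7  # phase 7, amp 65: inside the 7-8 x 60-90 region
  expect_equal(pac_summary(cm, phase_range = c(7, 7), amp_range = c(65, 65)), 0.7)
  expect_error(pac_summary(cm, phase_range = c(20, 30)), "empty")

  summaries <- vapply(c(0, 0.4, 0.8), function(k) {
    p <- synth_params(seed = 57, bout_schedule = data.frame(state = "REM", duration_s = 60),
                      channels = "DG", rem = list(pac_strength = k))
    x <- generate_recording(p)$signals[, "DG"]
    modulation_index(x, 2000, c(6.5, 8.5), c(60, 90))
  }, numeric(1))
  expect_true(all(diff(summaries) > 0))
})
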