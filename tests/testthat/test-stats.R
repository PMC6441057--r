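test_that("two-sample t-test handles identical, shifted and degenerate inputs", {
  a <- c(1, 2, 3)
  r0 <- two_sample_ttest(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  r1 <- two_sample_ttest(a, a + 100)
  expect_lt(r1$p, 0.001)
  # closed form: pooled t with equal spreads and mean shift 100
  sp <- sqrt(1)  # pooled variance of {1,2,3} vs itself
  expect_equal(abs(r1$t), 100 / (sp * sqrt(2 / 3)), tolerance = 1e-9)

  expect_equal(two_sample_ttest(c(5, 5), c(5, 5))$p, 1)
  expect_equal(two_sample_ttest(c(5, 5), c(7, 7))$p, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), "length")
})

test_that("t-test type-I error is nominal under the null", {
  set.seed(81)
  n_rep <- 4000
  A <- matrix(rnorm(8 * n_rep), nrow = 8)
  B <- matrix(rnorm(6 * n_rep), nrow = 6)
  p <- vapply(seq_len(n_rep), function(i) two_sample_ttest(A[, i], B[, i])$p,
              numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("exhaustive permutation test matches full enumeration and is deterministic", {
  r <- permutation_test(c(1, 2), c(3, 4))
  expect_true(r$exhaustive)
  expect_equal(r$n_perm_used, 6)
  expect_equal(r$p, 2 / 6)
  # seed-independent in the exhaustive branch
  expect_equal(permutation_test(c(1, 2), c(3, 4), seed = 99)$p, 2 / 6)

  expect_equal(permutation_test(c(2, 2), c(2, 2))$p, 1)
})

test_that("sampled permutation p-values are valid and approximately uniform under the null", {
  set.seed(82)
  p1 <- permutation_test(rnorm(30), rnorm(30), n_perm = 1000, seed = 1)
  expect_false(p1$exhaustive)
  expect_gte(p1$p, 1 / 1001)

  # exhaustive n = 8 vs 6 null: p is discrete-uniform enough for a KS check
  ps <- replicate(400, {
    permutation_test(rnorm(8), rnorm(6), n_perm = 10000)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH adjustment reproduces the step-up rule and a brute-force oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.04, 0.5), alpha = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$q, c(0.04, 0.04, 160 / 3000, 0.5), tolerance = 1e-9)

  r2 <- bh_fdr(rep(0.5, 5))
  expect_false(any(r2$reject))
  expect_true(all(r2$q == 0.5))
  expect_equal(bh_fdr(0.031)$q, 0.031)

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- numeric(m)
    for (i in seq_len(m)) {
      q_sorted[i] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
    }
    q <- numeric(m); q[o] <- q_sorted
    q
  }
  set.seed(83)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$q, brute_bh(p), tolerance = 1e-12)
  }
})

test_that("spectrum comparison rejects only where groups differ, controlling FDR", {
  make_spec <- function(psd) sleepcouple:::new_spectrum(seq(1, 100, 0.5), psd)
  f <- seq(1, 100, 0.5)
  set.seed(84)
  ga <- lapply(1:6, function(i) make_spec(rexp(length(f))))
  gb <- lapply(1:6, function(i) make_spec(rexp(length(f))))
  expect_false(any(compare_spectra(ga, gb)$significant))
  # identical groups: empty rejection set
  expect_false(any(compare_spectra(ga, ga)$significant))

  # band-limited elevation in group b between 15 and 50 Hz
  hits <- replicate(5, {
    ga <- lapply(1:6, function(i) make_spec(1 + 0.1 * rnorm(length(f))))
    gb <- lapply(1:6, function(i) {
      up <- ifelse(f >= 15 & f <= 50, 2, 1)
      make_spec(up + 0.1 * rnorm(length(f)))
    })
    cs <- compare_spectra(ga, gb)
    c(in_band = mean(cs$significant[cs$freq_hz >= 15 & cs$freq_hz <= 50]),
      low = sum(cs$significant[cs$freq_hz < 10]))
  })
  expect_gt(mean(hits["in_band", ]), 0.9)
  expect_lt(mean(hits["low", ]), 1)

  # masked bins are excluded from the family
  ga50 <- lapply(ga, function(s) notch_mask(s, 50, 1))
  cs <- compare_spectra(ga50, gb)
  expect_false(any(abs(cs$freq_hz - 50) <= 1))

  bad <- sleepcouple:::new_spectrum(seq(1, 50, 0.5), rep(1, 99))
  expect_error(compare_spectra(list(bad), ga), "grids differ")
})

test_that("empirical FDR of the spectrum pipeline stays controlled under the null", {
  set.seed(85)
  f <- seq(1, 100, 0.5)
  fd <- replicate(40, {
    ga <- lapply(1:5, function(i) sleepcouple:::new_spectrum(f, rexp(length(f))))
    gb <- lapply(1:5, function(i) sleepcouple:::new_spectrum(f, rexp(length(f))))
    any(compare_spectra(ga, gb)$significant)
  })
  # family-wise null rejections occur in at most ~alpha of families (BH under
  # the global null behaves like Bonferroni at the family level)
  expect_lte(mean(fd), 0.05 + 2 * sqrt(0.05 * 0.95 / 40))
})
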