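# Internal signal-processing primitives shared across modules.
#
# All filtering is zero-phase by construction: band-passes are applied in the
# frequency domain with unit passband gain and raised-cosine transition bands.
# For the long segments this package works on (tens of seconds at 1-2 kHz) the
# circular wrap-around of FFT filtering is confined to a fraction of a second
# at the segment edges; callers that are sensitive to it (PAC) trim the edges.

hamming_win <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Tapered-flat (Tukey) window: flat top with cosine ramps covering a fraction
# `alpha` of the total length (alpha/2 per edge).
tukey_win <- function(n, alpha = 0.2) {
  if (alpha <= 0) return(rep(1, n))
  if (alpha >= 1) return(0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1))))
  w <- rep(1, n)
  edge <- floor(alpha * (n - 1) / 2)
  if (edge > 0) {
    i <- 0:edge
    ramp <- 0.5 * (1 + cos(pi * (2 * i / (alpha * (n - 1)) - 1)))
    w[1 + i] <- ramp
    w[n - i] <- ramp
  }
  w
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Frequency response evaluated on the folded frequency axis: 1 inside
# [lo, hi], raised-cosine ramps of width `trans` outside, 0 beyond.
.bp_gain <- function(f, lo, hi, trans) {
  g <- numeric(length(f))
  g[f >= lo & f <= hi] <- 1
  if (trans > 0) {
    lo0 <- max(lo - trans, 0)
    ramp_up <- f > lo0 & f < lo
    if (lo > 0 && any(ramp_up)) {
      g[ramp_up] <- 0.5 * (1 - cos(pi * (f[ramp_up] - lo0) / (lo - lo0)))
    }
    ramp_dn <- f > hi & f < hi + trans
    g[ramp_dn] <- 0.5 * (1 + cos(pi * (f[ramp_dn] - hi) / trans))
  }
  if (lo <= 0) g[f < lo] <- 1  # low-pass: keep DC side
  g
}

# Zero-phase band-pass. lo <= 0 gives a low-pass, hi >= fs/2 a high-pass.
bp_filter <- function(x, fs, lo, hi, trans_hz = NULL) {
  n <- length(x)
  if (is.null(trans_hz)) trans_hz <- max(0.5, 0.15 * (hi - lo))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  g <- .bp_gain(f, lo, min(hi, fs / 2), trans_hz)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE) / n)
}

# Centered moving average with shrinking windows at the edges (no NA).
smooth_ma <- function(x, n) {
  if (n <= 1) return(x)
  len <- length(x)
  half <- floor(n / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(len) - half, 1)
  hi <- pmin(seq_len(len) + half, len)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Welch-averaged auto- (and optionally cross-) spectra.  One-sided density
# normalization: sum(Pxx) * df approximates var(x) for a zero-mean signal.
welch_engine <- function(x, y = NULL, fs, window_s = 2, overlap_frac = 0.5,
                         demean = TRUE) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) {
    stop("segment shorter than the Welch window (", length(x), " < ", nwin, " samples)")
  }
  step <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  K <- length(starts)
  w <- hamming_win(nwin)
  seg_mat <- function(z) {
    m <- vapply(starts, function(s) z[s:(s + nwin - 1L)], numeric(nwin))
    m <- matrix(m, nrow = nwin)
    if (demean) m <- sweep(m, 2, colMeans(m))
    m * w
  }
  X <- stats::mvfft(seg_mat(x))
  nkeep <- floor(nwin / 2) + 1L
  scale <- 1 / (fs * sum(w^2))
  side <- rep(2, nkeep)
  side[1] <- 1
  if (nwin %% 2 == 0) side[nkeep] <- 1
  Xk <- X[seq_len(nkeep), , drop = FALSE]
  pxx <- rowMeans(Mod(Xk)^2) * scale * side
  out <- list(freqs = (seq_len(nkeep) - 1) * fs / nwin, pxx = pxx, K = K)
  if (!is.null(y)) {
    if (length(y) != length(x)) stop("x and y must have equal length")
    Y <- stats::mvfft(seg_mat(y))
    Yk <- Y[seq_len(nkeep), , drop = FALSE]
    out$pyy <- rowMeans(Mod(Yk)^2) * scale * side
    out$pxy <- rowMeans(Xk * Conj(Yk)) * scale * side
  }
  out
}

# 1/f^alpha coloured noise with unit standard deviation, via spectral shaping.
colored_noise <- function(n, alpha = 1) {
  wn <- stats::rnorm(n)
  X <- stats::fft(wn)
  f <- (seq_len(n) - 1)
  f <- pmin(f, n - f)
  shape <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Linear convolution via FFT with 2-3-5-smooth padding (mixed-radix FFT is
# quadratic on awkward lengths), returning the full length(x)+length(h)-1.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  N <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(N - length(x))))
  H <- stats::fft(c(h, numeric(N - length(h))))
  Re(stats::fft(X * H, inverse = TRUE) / N)[seq_len(n)]
}

# Band-limited Gaussian noise with unit standard deviation.
band_noise <- function(n, fs, lo, hi) {
  x <- bp_filter(stats::rnorm(n), fs, lo, hi)
  x / stats::sd(x)
}
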