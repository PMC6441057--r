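# Group-comparison machinery: two-sample t-tests, permutation tests,
# Benjamini-Hochberg FDR, and per-frequency-bin spectrum comparison.

#' Two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] (pooled-variance by default, the
#' classic two-sample test; Welch via `var_equal = FALSE`), with the
#' degenerate all-constant case handled by convention.
#'
#' @param a,b numeric vectors, each of length at least 2.
#' @param var_equal pooled variance if `TRUE` (default).
#' @return list `t`, `p`, `df`, `n` (per-group sizes).
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  n = c(length(a), length(b))))
    }
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0,
                df = length(a) + length(b) - 2, n = c(length(a), length(b))))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       n = c(length(a), length(b)))
}

#' Permutation test for a two-group difference
#'
#' Two-sided test on the group-assignment permutation distribution of a
#' statistic (mean difference by default).  When the number of distinct
#' assignments `choose(n, n_a)` does not exceed `n_perm` the distribution is
#' enumerated exhaustively, making the p-value deterministic and
#' seed-independent; otherwise `n_perm` random assignments are drawn and
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`.
#'
#' @param a,b numeric vectors; combined length at least 4.
#' @param statistic function of two vectors returning a scalar; `NULL`
#'   (default) uses the difference of means via a vectorized path.
#' @param n_perm maximum number of permutations (default 10000).
#' @param seed RNG seed for the sampled branch.
#' @return list `p`, `statistic` (observed), `n_perm_used`, `exhaustive`.
#' @export
permutation_test <- function(a, b, statistic = NULL, n_perm = 10000,
                             seed = NULL) {
  stopifnot(length(a) + length(b) >= 4, n_perm >= 1000)
  pool <- c(a, b)
  n <- length(pool); na <- length(a); nb <- n - na
  mean_diff <- is.null(statistic)
  stat2 <- if (mean_diff) function(x, y) mean(x) - mean(y) else statistic
  obs <- stat2(a, b)
  tol <- 1e-12 * max(1, abs(obs))
  n_total <- choose(n, na)
  if (n_total <= n_perm) {
    idx <- combn(n, na)
    perm <- if (mean_diff) {
      s_tot <- sum(pool)
      s_a <- colSums(matrix(pool[idx], nrow = na))
      s_a / na - (s_tot - s_a) / nb
    } else {
      apply(idx, 2, function(i) stat2(pool[i], pool[-i]))
    }
    p <- sum(abs(perm) >= abs(obs) - tol) / n_total
    return(list(p = p, statistic = obs, n_perm_used = n_total, exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, {
    i <- sample.int(n, na)
    stat2(pool[i], pool[-i])
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - tol)) / (1 + n_perm)
  list(p = p, statistic = obs, n_perm_used = n_perm, exhaustive = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (`q_i = min over j >= i of m p_(j) / j`) and the
#' rejection set at level `alpha`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list `q` (same order as input), `reject` (logical).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  q <- p.adjust(pvalues, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Compare two groups of spectra bin by bin
#'
#' Per unmasked frequency bin, a two-sample t-test of group A vs group B psd
#' values across animals; Benjamini-Hochberg correction over the bins of
#' this one panel (one channel x state family).
#'
#' @param spectra_a,spectra_b lists of `sc_spectrum` (one per animal), all on
#'   the same frequency grid.
#' @param alpha FDR level.
#' @param var_equal pooled-variance t-test if `TRUE`.
#' @return data.frame `freq_hz`, `t`, `p`, `q`, `significant` (masked bins
#'   are absent).
#' @export
compare_spectra <- function(spectra_a, spectra_b, alpha = 0.05, var_equal = TRUE) {
  f0 <- spectra_a[[1]]$freqs
  all_s <- c(spectra_a, spectra_b)
  for (s in all_s) {
    if (!isTRUE(all.equal(s$freqs, f0))) stop("integrity error: frequency grids differ")
  }
  masked <- Reduce(`|`, lapply(all_s, function(s) s$masked))
  keep <- which(!masked)
  A <- vapply(spectra_a, function(s) s$psd, numeric(length(f0)))[keep, , drop = FALSE]
  B <- vapply(spectra_b, function(s) s$psd, numeric(length(f0)))[keep, , drop = FALSE]
  res <- t(vapply(seq_along(keep), function(i) {
    tt <- two_sample_ttest(A[i, ], B[i, ], var_equal = var_equal)
    c(tt$t, tt$p)
  }, numeric(2)))
  adj <- bh_fdr(res[, 2], alpha)
  data.frame(freq_hz = f0[keep], t = res[, 1], p = res[, 2], q = adj$q,
             significant = adj$reject)
}
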