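# Magnitude-squared coherence between region pairs, band-averaged per state.

#' Magnitude-squared coherence spectrum
#'
#' `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` with Welch-averaged auto- and
#' cross-spectra, bounded in `[0, 1]`.  The estimator is biased upward for
#' independent signals by about `1/K`, where `K` is the number of averaged
#' segments; a single segment gives identically 1 and is rejected.
#'
#' @param x,y equal-length signal segments.
#' @param fs sampling rate, Hz.
#' @param window_s,overlap_frac Welch parameters (defaults 2 s, 50%: a 20-s
#'   epoch gives K = 19 segments).
#' @param fmax optional upper frequency cut.
#' @param pair optional character pair label of length 2.
#' @param state optional state label.
#' @return an `sc_coherence`: `freqs`, `cxy`, `masked`, retained components
#'   `pxx`, `pyy`, `pxy`, segment count `K`, `pair`, `state`.
#' @export
msc <- function(x, y, fs, window_s = 2, overlap_frac = 0.5, fmax = NULL,
                pair = c(NA_character_, NA_character_), state = NA_character_) {
  if (length(x) != length(y)) stop("input error: x and y must have equal length")
  w <- welch_engine(x, y, fs = fs, window_s = window_s, overlap_frac = overlap_frac)
  if (w$K < 2) {
    stop("input error: coherence needs at least 2 averaging segments ",
         "(single-segment coherence is identically 1)")
  }
  keep <- if (is.null(fmax)) seq_along(w$freqs) else which(w$freqs <= fmax)
  denom <- w$pxx * w$pyy
  cxy <- ifelse(denom > 0, Mod(w$pxy)^2 / denom, 0)
  cxy <- pmin(pmax(cxy, 0), 1)
  structure(list(freqs = w$freqs[keep], cxy = cxy[keep],
                 masked = rep(FALSE, length(keep)),
                 pxx = w$pxx[keep], pyy = w$pyy[keep], pxy = w$pxy[keep],
                 K = w$K, pair = pair, state = state),
            class = "sc_coherence")
}

#' @export
print.sc_coherence <- function(x, ...) {
  cat(sprintf("<coherence> %s-%s, %d bins, K=%d segments\n",
              x$pair[1], x$pair[2], length(x$freqs), x$K))
  invisible(x)
}

#' Band-averaged coherence
#'
#' Unweighted mean of the coherence over in-band frequency bins, masked
#' (line) bins excluded.
#'
#' @param cs an `sc_coherence`.
#' @param bands band table as from [band_definitions()].
#' @return data.frame `band`, `value` (one row per band, values in `[0,1]`).
#' @export
band_connectivity <- function(cs, bands = band_definitions()) {
  stopifnot(inherits(cs, "sc_coherence"))
  value <- vapply(seq_len(nrow(bands)), function(i) {
    j <- which(cs$freqs >= bands$lo_hz[i] & cs$freqs <= bands$hi_hz[i] & !cs$masked)
    if (!length(j)) stop("input error: band ", bands$name[i], " empty after masking")
    mean(cs$cxy[j])
  }, numeric(1))
  data.frame(band = bands$name, value = value, stringsAsFactors = FALSE)
}

#' Cohort band-connectivity table
#'
#' For each animal and each region pair, computes magnitude-squared coherence
#' on every 20-s NREM and REM epoch segment, averages the coherence spectra
#' within state (animal is the experimental unit), then averages over the
#' four canonical bands.
#'
#' @param recordings list of [recording()]s with `meta$animal` and
#'   `meta$genotype`.
#' @param hypnograms list of [hypnogram()]s, parallel to `recordings`.
#' @param pairs character vector of region pairs, e.g.
#'   `c("mFC-CA1", "mFC-RS", "CA1-DG")`.
#' @param bands band table as from [band_definitions()].
#' @param line_hz,line_half_width_hz line mask applied to every coherence
#'   spectrum before band averaging (set `line_hz = NULL` to skip).
#' @return tidy data.frame `animal`, `genotype`, `state`, `pair`, `band`,
#'   `coherence`.  Animals with no valid epoch pair are dropped with a
#'   warning.
#' @export
connectivity_table <- function(recordings, hypnograms, pairs, bands = band_definitions(),
                               line_hz = 50, line_half_width_hz = 1) {
  rows <- list()
  for (k in seq_along(recordings)) {
    r <- recordings[[k]]
    ep <- select_epoch_pairs(hypnograms[[k]])
    if (!nrow(ep)) {
      warning("animal ", r$meta$animal %||% k, " has no valid NREM/REM epoch pair; dropped")
      next
    }
    seg_s <- attr(ep, "segment_s")
    for (pr in pairs) {
      ab <- strsplit(pr, "-", fixed = TRUE)[[1]]
      x_full <- chan(r, ab[1]); y_full <- chan(r, ab[2])
      for (state in c("NREM", "REM")) {
        starts <- if (state == "NREM") ep$nrem_start_s else ep$rem_start_s
        cxy_sum <- NULL
        cs <- NULL
        for (t0 in starts) {
          i <- (round(t0 * r$fs) + 1):round((t0 + seg_s) * r$fs)
          cs <- msc(x_full[i], y_full[i], r$fs, pair = ab, state = state)
          cxy_sum <- if (is.null(cxy_sum)) cs$cxy else cxy_sum + cs$cxy
        }
        cs$cxy <- cxy_sum / length(starts)
        if (!is.null(line_hz)) cs <- notch_mask(cs, line_hz, line_half_width_hz)
        bc <- band_connectivity(cs, bands)
        rows[[length(rows) + 1]] <- data.frame(
          animal = r$meta$animal %||% as.character(k),
          genotype = r$meta$genotype %||% NA_character_,
          state = state, pair = pr, band = bc$band, coherence = bc$value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no animal contributed any epoch")
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
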