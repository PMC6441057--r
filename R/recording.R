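#' @import stats
#' @import utils
NULL

REGIONS <- c("sFC", "MC", "mFC", "Th-RT", "RS", "CA1", "DG", "EMG", "other")
KINDS <- c("screw", "wire", "emg")
STATES <- c("NREM", "REM", "WI", "MOVE")

.default_kind <- function(region) {
  ifelse(region == "EMG", "emg", ifelse(region %in% c("sFC", "MC"), "screw", "wire"))
}

#' Multichannel recording container
#'
#' A `recording` bundles a sample matrix (microvolts), the sampling rate, and
#' per-channel metadata (name, brain region, electrode kind).  All analysis
#' functions in the package take and return time in seconds from recording
#' start; sample `i` covers the half-open interval `[(i-1)/fs, i/fs)`.
#'
#' @param signals numeric matrix, samples in rows and channels in columns;
#'   column names are channel names (unique).  A named list of equal-length
#'   numeric vectors is also accepted.
#' @param fs sampling rate in Hz (default 2000).
#' @param regions character vector of per-channel brain regions, one of
#'   `r paste(REGIONS, collapse=", ")`.  Defaults to the channel names when
#'   those are valid region labels.
#' @param kinds electrode kinds (`screw`, `wire`, `emg`); inferred from the
#'   region when missing (`EMG` -> `emg`, `sFC`/`MC` -> `screw`, else `wire`).
#' @param meta free-form named list of annotations (animal id, genotype, ...).
#' @param ground_truth optional ground-truth list for synthetic recordings
#'   (see [generate_recording()]).
#' @return an object of class `recording` with fields `signals`, `fs`,
#'   `channels` (data.frame `name`, `region`, `kind`), `duration_s`, `meta`,
#'   and optionally `ground_truth`.
#' @export
recording <- function(signals, fs = 2000, regions = NULL, kinds = NULL,
                      meta = list(), ground_truth = NULL) {
  if (is.list(signals) && !is.matrix(signals)) {
    lens <- lengths(signals)
    if (length(unique(lens)) != 1) {
      stop("integrity error: channels have unequal lengths")
    }
    signals <- do.call(cbind, lapply(signals, as.numeric))
  }
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  nm <- colnames(signals)
  if (is.null(nm)) stop("signals must carry channel names")
  if (anyDuplicated(nm)) stop("channel names must be unique")
  if (is.null(regions)) {
    regions <- ifelse(nm %in% REGIONS, nm, "other")
  }
  regions <- match.arg(regions, REGIONS, several.ok = TRUE)
  if (length(regions) != ncol(signals)) stop("one region per channel required")
  if (is.null(kinds)) kinds <- .default_kind(regions)
  kinds <- match.arg(kinds, KINDS, several.ok = TRUE)
  if (length(kinds) != ncol(signals)) stop("one kind per channel required")
  if (any((regions == "EMG") != (kinds == "emg"))) {
    stop("region EMG if and only if kind emg")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive number")
  structure(
    list(
      signals = signals,
      fs = fs,
      channels = data.frame(name = nm, region = regions, kind = kinds,
                            stringsAsFactors = FALSE),
      duration_s = nrow(signals) / fs,
      meta = meta,
      ground_truth = ground_truth
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %.1f s @ %g Hz\n",
              ncol(x$signals), x$duration_s, x$fs))
  cat("  channels:", paste(x$channels$name, collapse = ", "), "\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$ground_truth)) cat("  [synthetic: ground truth attached]\n")
  invisible(x)
}

n_samples <- function(r) nrow(r$signals)

channel_names <- function(r) r$channels$name

# Single channel as a numeric vector; accepts a channel name or a region
# label (first matching channel).
chan <- function(r, channel) {
  i <- match(channel, r$channels$name)
  if (is.na(i)) i <- match(channel, r$channels$region)
  if (is.na(i)) stop("configuration error: no channel '", channel, "'")
  r$signals[, i]
}

# First channel of a given electrode kind, or NULL.
chan_by_kind <- function(r, kind) {
  i <- which(r$channels$kind == kind)
  if (!length(i)) return(NULL)
  r$channels$name[i[1]]
}

#' Extract a time slice of a recording
#'
#' @param r a [recording()].
#' @param start_s,end_s slice bounds in seconds, `0 <= start_s < end_s <=
#'   duration_s`; the slice covers `[start_s, end_s)`.
#' @param channels optional character vector of channel names to keep.
#' @return a `recording` of duration `end_s - start_s` (within one sample);
#'   metadata and channel info are preserved, ground truth is dropped.
#' @export
slice_recording <- function(r, start_s, end_s, channels = NULL) {
  stopifnot(inherits(r, "recording"))
  if (!(start_s >= 0 && start_s < end_s && end_s <= r$duration_s + 1e-9)) {
    stop("bounds error: need 0 <= start_s < end_s <= duration_s")
  }
  i0 <- floor(start_s * r$fs) + 1
  i1 <- min(floor(end_s * r$fs), n_samples(r))
  keep <- if (is.null(channels)) r$channels$name else channels
  j <- match(keep, r$channels$name)
  if (anyNA(j)) stop("configuration error: unknown channel(s) ",
                     paste(keep[is.na(j)], collapse = ", "))
  sig <- r$signals[i0:i1, j, drop = FALSE]
  colnames(sig) <- keep
  recording(sig, fs = r$fs, regions = r$channels$region[j],
            kinds = r$channels$kind[j], meta = r$meta)
}

#' Hypnogram: per-bin sleep-state labels
#'
#' @param labels character vector over `NREM`, `REM`, `WI`, `MOVE`.
#' @param bin_s bin length in seconds (default 2).
#' @param derived_from channel names the labels were derived from.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(labels, bin_s = 2, derived_from = character()) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), STATES)
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels, bin_s = bin_s, derived_from = derived_from),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = STATES))
  cat(sprintf("<hypnogram> %d bins x %g s\n", length(x$labels), x$bin_s))
  print(tab)
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

# State label at time t (seconds); NA outside the covered range.
state_at <- function(h, t_s) {
  k <- floor(t_s / h$bin_s) + 1
  out <- rep(NA_character_, length(k))
  ok <- k >= 1 & k <= length(h$labels)
  out[ok] <- h$labels[k[ok]]
  out
}

# Per-sample state labels for a recording of n samples.
state_per_sample <- function(h, n, fs) {
  k <- pmin(floor((seq_len(n) - 1) / fs / h$bin_s) + 1, length(h$labels))
  h$labels[k]
}

#' Event table constructor
#'
#' Rows describe transient events (ripples, spindles) with half-open time
#' support `[start_s, end_s)` and a peak time inside it.
#'
#' @param start_s,peak_s,end_s event times in seconds with
#'   `start_s <= peak_s <= end_s`.
#' @param channel,kind character columns.
#' @param ... further attribute columns (recycled to length).
#' @return a data.frame of class `event_table`, sorted by `start_s`.
#' @export
event_table <- function(start_s = numeric(), peak_s = numeric(),
                        end_s = numeric(), channel = character(),
                        kind = character(), ...) {
  df <- data.frame(start_s = as.numeric(start_s), peak_s = as.numeric(peak_s),
                   end_s = as.numeric(end_s),
                   channel = as.character(channel), kind = as.character(kind),
                   ..., stringsAsFactors = FALSE)
  validate_event_table(df)
}

validate_event_table <- function(df) {
  if (nrow(df)) {
    if (any(df$start_s > df$peak_s | df$peak_s > df$end_s)) {
      stop("integrity error: need start_s <= peak_s <= end_s")
    }
    df <- df[order(df$start_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("event_table", "data.frame")
  df
}
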