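# Readers/writers: internal binary container (lossless at float32),
# EDF (read-only, for interoperability), events and hypnograms as CSV.

CONTAINER_MAGIC <- "SLPCREC1"

#' Write a recording to the internal container format
#'
#' The container is a single self-describing file: an 8-byte magic string, a
#' little-endian uint32 header length, a JSON header (sampling rate, channel
#' table, metadata, ground truth if present), then the samples as float32 in
#' column-major (channel-contiguous) order.  Samples are stored in microvolts.
#' The format round-trips exactly at float32 precision; EDF's 16-bit integer
#' scaling, by contrast, is lossy, which is why EDF is supported read-only.
#'
#' @param r a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(r, path) {
  stopifnot(inherits(r, "recording"))
  header <- list(
    fs = r$fs,
    n_samples = n_samples(r),
    channels = r$channels,
    meta = r$meta
  )
  if (!is.null(r$ground_truth)) {
    gt <- r$ground_truth
    header$ground_truth <- list(
      hypnogram = list(labels = gt$hypnogram$labels, bin_s = gt$hypnogram$bin_s,
                       derived_from = gt$hypnogram$derived_from),
      events = as.data.frame(gt$events),
      params = gt$params
    )
  }
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  writeBin(as.integer(length(hjson)), con, size = 4, endian = "little")
  writeBin(hjson, con)
  writeBin(as.numeric(r$signals), con, size = 4, endian = "little")
  invisible(path)
}

read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(CONTAINER_MAGIC)))
  if (!identical(magic, CONTAINER_MAGIC)) {
    stop("format error: not a recording container (bad magic)")
  }
  hlen <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)),
                               simplifyDataFrame = TRUE)
  nch <- nrow(header$channels)
  n <- header$n_samples
  x <- readBin(con, "numeric", n = n * nch, size = 4, endian = "little")
  if (length(x) != n * nch) stop("integrity error: truncated sample payload")
  sig <- matrix(x, nrow = n, ncol = nch)
  colnames(sig) <- header$channels$name
  gt <- NULL
  if (!is.null(header$ground_truth)) {
    g <- header$ground_truth
    ev <- as.data.frame(g$events)
    if (!nrow(ev)) ev <- event_table()
    gt <- list(
      hypnogram = hypnogram(g$hypnogram$labels, g$hypnogram$bin_s,
                            as.character(unlist(g$hypnogram$derived_from))),
      events = validate_event_table(ev),
      params = g$params
    )
  }
  recording(sig, fs = header$fs, regions = header$channels$region,
            kinds = header$channels$kind,
            meta = as.list(header$meta), ground_truth = gt)
}

# Minimal EDF (European Data Format, 16-bit) reader.  Supports continuous
# recordings where every signal shares one sampling rate; per-signal rates
# would require resampling, which is out of scope, so they raise an error.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n = n))
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)          # version, patient, recording, date, time
  num(8)                                        # header length
  rd(44)                                        # reserved
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- fld(16)
  fld(80)                                       # transducer
  fld(8)                                        # physical dimension
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                                       # prefiltering
  spr <- as.integer(fld(8))                     # samples per record
  fld(32)                                       # reserved
  if (length(unique(spr)) != 1) {
    stop("integrity error: per-signal sampling rates differ (resampling out of scope)")
  }
  fs <- spr[1] / rec_dur
  raw_counts <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                        signed = TRUE, endian = "little")
  if (length(raw_counts) != n_rec * sum(spr)) {
    stop("integrity error: truncated EDF data section")
  }
  # records are interleaved: [rec1 sig1..sigNs][rec2 ...]
  arr <- array(raw_counts, dim = c(spr[1], ns, n_rec))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- vapply(seq_len(ns), function(i) {
    as.vector(arr[, i, ]) * scale[i] + (phys_min[i] - dig_min[i] * scale[i])
  }, numeric(spr[1] * n_rec))
  labels <- make.unique(labels)
  colnames(sig) <- labels
  regions <- ifelse(labels %in% REGIONS, labels,
                    ifelse(grepl("emg", labels, ignore.case = TRUE), "EMG", "other"))
  recording(sig, fs = fs, regions = regions)
}

#' Read a recording
#'
#' @param path file path.
#' @param format `container` (internal format written by [write_recording()])
#'   or `edf` (16-bit European Data Format, read-only; all signals must share
#'   one sampling rate).
#' @return a [recording()]; sample values in microvolts.
#' @export
read_recording <- function(path, format = c("container", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, container = read_container(path), edf = read_edf(path))
}

#' Write / read an event table as CSV
#'
#' Times are printed with microsecond precision; a written table re-read and
#' re-written is byte-identical.
#'
#' @param t an [event_table()].
#' @param path CSV path with header `start_s,peak_s,end_s,channel,kind,...`.
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   `event_table`.
#' @export
write_events <- function(t, path) {
  t <- validate_event_table(as.data.frame(t))
  out <- as.data.frame(t)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.6f", out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "peak_s", "end_s", "channel", "kind")
  if (!all(need %in% names(df))) {
    stop("format error: event CSV must have columns ", paste(need, collapse = ","))
  }
  df$channel <- as.character(df$channel)
  df$kind <- as.character(df$kind)
  validate_event_table(df)
}

#' Write / read a hypnogram as CSV
#'
#' @param h a [hypnogram()].
#' @param path CSV path with header `bin_index,start_s,label` (0-based bins).
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  n <- length(h$labels)
  df <- data.frame(bin_index = seq_len(n) - 1,
                   start_s = sprintf("%.3f", (seq_len(n) - 1) * h$bin_s),
                   label = h$labels)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  bin_s <- if (nrow(df) >= 2) df$start_s[2] - df$start_s[1] else 2
  hypnogram(df$label, bin_s = bin_s)
}
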