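# Byte-level EDF writer used only to exercise the package's EDF reader.

write_test_edf <- function(path, signals, fs, record_s = 1,
                           samples_per_record = NULL) {
  ns <- ncol(signals)
  if (is.null(samples_per_record)) samples_per_record <- rep(fs * record_s, ns)
  n_rec <- nrow(signals) / max(samples_per_record)
  stopifnot(n_rec == round(n_rec))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad("0", 8)); wr(pad("patient", 80)); wr(pad("recording", 80))
  wr(pad("01.01.20", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 + 256 * ns, 8)); wr(pad("", 44))
  wr(pad(n_rec, 8)); wr(pad(record_s, 8)); wr(pad(ns, 4))
  labs <- colnames(signals)
  for (i in 1:ns) wr(pad(labs[i], 16))
  for (i in 1:ns) wr(pad("wire", 80))
  for (i in 1:ns) wr(pad("uV", 8))
  pmin_ <- rep(-3277, ns); pmax_ <- rep(3276.9, ns)
  for (i in 1:ns) wr(pad(pmin_[i], 8))
  for (i in 1:ns) wr(pad(pmax_[i], 8))
  for (i in 1:ns) wr(pad(-32768, 8))
  for (i in 1:ns) wr(pad(32767, 8))
  for (i in 1:ns) wr(pad("", 80))
  for (i in 1:ns) wr(pad(samples_per_record[i], 8))
  for (i in 1:ns) wr(pad("", 32))
  # digital counts: phys = dig * 0.1  (range symmetric)
  scale <- (pmax_ - pmin_) / (32767 - (-32768))
  for (rec in seq_len(n_rec)) {
    for (i in 1:ns) {
      spr <- samples_per_record[i]
      seg <- signals[((rec - 1) * spr + 1):(rec * spr), i]
      dig <- as.integer(round((seg - pmin_[i]) / scale[i] + (-32768)))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
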