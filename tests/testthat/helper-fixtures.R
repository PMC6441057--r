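# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Default 10-minute 7-channel synthetic animal.
default_animal <- function(seed = 1) {
  fixture(paste0("animal", seed), function() {
    generate_recording(synth_params(seed = seed))
  })
}

# 10-minute NREM-only CA1 recording with ripples (detector fixtures).
ripple_recording <- function(seed = 1, ...) {
  key <- paste0("rip", seed, paste(deparse(list(...)), collapse = ""))
  fixture(key, function() {
    generate_recording(synth_params(
      seed = seed,
      bout_schedule = data.frame(state = "NREM", duration_s = 600),
      channels = "CA1", ...))
  })
}

# Small recording built by hand (not via the generator).
toy_recording <- function(duration_s = 10, fs = 200, n_chan = 3, seed = 99) {
  set.seed(seed)
  n <- duration_s * fs
  sig <- matrix(rnorm(n * n_chan), n, n_chan)
  colnames(sig) <- c("sFC", "CA1", "EMG")[seq_len(n_chan)]
  recording(sig, fs = fs, meta = list(animal = "toy"))
}

# Quantize a recording's samples to float32 (the container precision).
quantize32 <- function(r) {
  con <- rawConnection(raw(0), "r+")
  writeBin(as.numeric(r$signals), con, size = 4, endian = "little")
  seek(con, 0)
  x <- readBin(con, "numeric", n = length(r$signals), size = 4, endian = "little")
  close(con)
  r$signals[] <- x
  r
}
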