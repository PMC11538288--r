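# Shared fixtures: small deterministic templates and a stereo-WAV writer
# used to exercise the multi-channel reader path.

fixedTemplate <- function(name = "fixed", f0 = 100, n = 7, res = 300,
                          tau = 6.8, snr = 20, pattern = 0, nBlocks = c(2, 0),
                          interval = c(18, 0)) {
  taxonTemplate(name, nPulses = c(n, 0), f0Hz = c(f0, 0),
                resonanceHz = c(res, 0), lastPulseTauMs = tau,
                patternProb = pattern, nBlocks = nBlocks,
                intervalMs = interval, snrDb = snr)
}

writeStereoWav <- function(left, right, path, rateHz = 44100) {
  stopifnot(length(left) == length(right))
  pcm <- as.integer(round(pmin(pmax(rbind(left, right), -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(rateHz), con, size = 4, endian = "little")
  writeBin(as.integer(rateHz * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  writeBin(as.vector(pcm), con, size = 2, endian = "little")
  invisible(path)
}

# independent re-statement of the interval rule, used as the brute-force
# oracle for segmentBlocks
bruteForceBlocks <- function(periods, ratio = 1.25) {
  np <- length(periods) + 1L
  if (np <= 3L || length(periods) == 0L) return(1L)
  thr <- ratio * mean(periods)
  isInt <- logical(length(periods))
  for (i in seq_along(periods)) {
    isInt[i] <- periods[i] > thr && i != length(periods)
  }
  sum(isInt) + 1L
}
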