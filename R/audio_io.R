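#' Construct a Waveform
#'
#' @param samples numeric amplitudes, nominally in \code{[-1, 1]}.
#' @param rateHz sampling rate in Hz (default 44100, the package's canonical
#'   internal rate).
#' @param t0Ms time origin of the first sample (ms).
#' @return a [Waveform-class].
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 1, by = 1 / 44100)))
#' durationMs(w)
#' @export
waveform <- function(samples, rateHz = 44100, t0Ms = 0) {
  new("Waveform", samples = as.numeric(samples), rateHz = rateHz, t0Ms = t0Ms)
}

#' Read a PCM WAV file as a mono Waveform
#'
#' Reads 8/16/24/32-bit integer or 32-bit float PCM. Multi-channel input is
#' reduced to mono by channel average; amplitudes are scaled to
#' \code{[-1, 1]}; input at a rate other than 44100 Hz is resampled (linear
#' interpolation) to the canonical 44100 Hz.
#'
#' @param path path to a WAV file.
#' @param targetRateHz internal rate to resample to (default 44100).
#' @return a [Waveform-class].
#' @seealso [writeWav()], [bandpassFilter()]
#' @export
readWav <- function(path, targetRateHz = 44100) {
  if (!file.exists(path))
    hcStop("holocall_missing_file", "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    hcStop("holocall_not_audio", "not a RIFF/WAVE file: %s", path)

  fmt <- NULL; dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmtRaw <- readBin(con, "raw", size)
      le16 <- function(i) sum(as.integer(fmtRaw[i:(i + 1)]) * c(1, 256))
      le32 <- function(i) sum(as.numeric(fmtRaw[i:(i + 3)]) * c(1, 256, 65536, 16777216))
      fmt <- list(format = le16(1), channels = le16(3),
                  rate = le32(5), bits = le16(15))
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw))
    hcStop("holocall_not_audio", "missing fmt/data chunk: %s", path)
  if (length(dataRaw) == 0)
    hcStop("holocall_zero_length", "zero-length audio: %s", path)

  x <- decodePcm(dataRaw, fmt$format, fmt$bits)
  nch <- fmt$channels
  if (nch > 1L) {
    nFrames <- length(x) %/% nch
    x <- x[seq_len(nFrames * nch)]
    dim(x) <- c(nch, nFrames)
    x <- colMeans(x)
  }
  if (length(x) == 0)
    hcStop("holocall_zero_length", "zero-length audio: %s", path)
  if (fmt$rate != targetRateHz)
    x <- resampleLinear(x, fmt$rate, targetRateHz)
  waveform(x, rateHz = targetRateHz)
}

decodePcm <- function(raw, format, bits) {
  if (format == 3L) {  # IEEE float
    if (bits != 32L) hcStop("holocall_not_audio", "unsupported float width: %d", bits)
    return(readBin(raw, "double", length(raw) %/% 4, size = 4, endian = "little"))
  }
  if (format != 1L)
    hcStop("holocall_not_audio", "unsupported WAV format code: %d", format)
  switch(as.character(bits),
    "8"  = (as.integer(raw) - 128) / 128,  # 8-bit PCM is unsigned
    "16" = readBin(raw, "integer", length(raw) %/% 2, size = 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(raw) %/% 3
      b <- matrix(as.numeric(raw[seq_len(n * 3)]), nrow = 3)
      v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    "32" = readBin(raw, "integer", length(raw) %/% 4, size = 4,
                   endian = "little") / 2147483648,
    hcStop("holocall_not_audio", "unsupported bit depth: %d", bits)
  )
}

resampleLinear <- function(x, fromHz, toHz) {
  n <- length(x)
  tOld <- (seq_len(n) - 1) / fromHz
  nNew <- max(1L, floor((n - 1) / fromHz * toHz) + 1L)
  tNew <- (seq_len(nNew) - 1) / toHz
  stats::approx(tOld, x, xout = pmin(tNew, tOld[n]))$y
}

#' Write a Waveform to a 16-bit PCM mono WAV file
#'
#' Amplitudes are clamped to \code{[-1, 1]} and quantized to 16 bits.
#'
#' @param w a [Waveform-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeWav <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  x <- pmin(pmax(w@samples, -1), 1)
  pcm <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(w@rateHz), con, size = 4, endian = "little")
  writeBin(as.integer(w@rateHz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Zero-phase band-pass conditioning
#'
#' Conditions a waveform the way the recordings were conditioned before
#' measurement: a 4th-order Butterworth band-pass (default 50-4000 Hz)
#' applied forward and backward (\code{signal::filtfilt}), so the magnitude
#' response is squared (at least 48 dB/octave beyond each edge) and the phase
#' is zero -- pulse peak times do not shift.
#'
#' @param w a [Waveform-class].
#' @param loHz lower band edge (Hz), default 50.
#' @param hiHz upper band edge (Hz), default 4000.
#' @param order Butterworth order of the one-way prototype (default 4).
#' @return a [Waveform-class] of the same length and rate.
#' @examples
#' w <- waveform(sin(2 * pi * 1000 * seq(0, 0.2, by = 1 / 44100)))
#' f <- bandpassFilter(w)
#' @export
bandpassFilter <- function(w, loHz = 50, hiHz = 4000, order = 4) {
  stopifnot(is(w, "Waveform"))
  nyq <- w@rateHz / 2
  if (!(loHz > 0 && loHz < hiHz && hiHz < nyq))
    hcStop("holocall_bad_band",
           "invalid band edges: need 0 < lo (%g) < hi (%g) < Nyquist (%g)",
           loHz, hiHz, nyq)
  bf <- signal::butter(order, c(loHz, hiHz) / nyq, type = "pass")
  x <- w@samples
  # odd (point-symmetric) extension keeps value and slope continuous at the
  # edges, so filtfilt start-up transients fall outside the call; the
  # transient scale is set by the low band edge. The reflection is anchored
  # on a ~1 ms edge mean: anchoring on the single edge sample would inject a
  # DC step of twice its noise value and ring through the high-pass.
  n <- length(x)
  npad <- min(n - 1L, as.integer(ceiling(3 * w@rateHz / loHz)))
  k <- max(1L, min(n, as.integer(round(0.001 * w@rateHz))))
  a1 <- mean(x[seq_len(k)])
  a2 <- mean(x[(n - k + 1L):n])
  xp <- c(2 * a1 - rev(x[2:(npad + 1L)]), x,
          2 * a2 - rev(x[(n - npad):(n - 1L)]))
  yp <- signal::filtfilt(bf, xp)
  y <- yp[npad + seq_len(n)]
  new("Waveform", samples = y, rateHz = w@rateHz, t0Ms = w@t0Ms)
}
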