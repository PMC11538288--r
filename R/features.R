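#' Power spectrum of a whole sound
#'
#' One windowed transform of the entire call (Hamming window), zero padded so
#' the bin spacing is at most \code{targetResolutionHz} (~5 Hz) regardless of
#' call duration.
#'
#' @param w a [Waveform-class].
#' @param window window name; only \code{"hamming"} is provided.
#' @param targetResolutionHz maximum bin spacing (Hz, default 5).
#' @return a [Spectrum-class] covering 0 to Nyquist.
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 1, by = 1 / 44100)))
#' sp <- powerSpectrum(w)
#' dominantFrequency(sp)
#' @export
powerSpectrum <- function(w, window = "hamming", targetResolutionHz = 5) {
  stopifnot(is(w, "Waveform"))
  window <- match.arg(window, "hamming")
  if (targetResolutionHz < 0.1)
    hcStop("holocall_bad_resolution",
           "target resolution %g Hz is pathologically fine (< 0.1 Hz)",
           targetResolutionHz)
  x <- w@samples
  n <- length(x)
  i <- seq_len(n) - 1
  win <- 0.54 - 0.46 * cos(2 * pi * i / (n - 1))
  if (n == 1) win <- 1
  xw <- x * win
  nfft <- max(n, ceiling(w@rateHz / targetResolutionHz))
  nfft <- 2^ceiling(log2(nfft))  # pad to a power of two at or past the target
  X <- stats::fft(c(xw, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1)
  p <- Mod(X[half])^2
  new("Spectrum",
      freqsHz = (half - 1) * w@rateHz / nfft,
      power = p,
      resolutionHz = w@rateHz / nfft)
}

#' Dominant frequency
#'
#' The frequency with the highest energy in the search band (the recording
#' band, 50-4000 Hz, by default). Ties break to the lowest frequency.
#'
#' @param spec a [Spectrum-class].
#' @param bandHz numeric c(lo, hi) search band in Hz.
#' @return frequency in Hz of the maximal-power bin.
#' @export
dominantFrequency <- function(spec, bandHz = c(50, 4000)) {
  stopifnot(is(spec, "Spectrum"))
  inBand <- spec@freqsHz >= bandHz[1] & spec@freqsHz <= bandHz[2]
  if (!any(inBand))
    hcStop("holocall_bad_band", "band [%g, %g] Hz outside the spectrum range",
           bandHz[1], bandHz[2])
  p <- spec@power[inBand]
  if (all(p == 0))
    hcStop("holocall_zero_spectrum", "all-zero spectrum in the search band")
  f <- spec@freqsHz[inBand]
  f[which.max(p)]  # which.max takes the first (lowest-frequency) maximum
}

#' Fundamental frequency of a pulsed call
#'
#' The primary frequency of the harmonic sound. Calls of more than two pulses
#' carry a harmonic comb whose line spacing equals the pulse repetition rate,
#' so the estimate is the spectral peak nearest the period-derived prior
#' \code{1000 / mean period (ms)}, searched within \code{searchRel} of the
#' prior, and cross-checked against it: if the two disagree by more than 20
#' percent the value is returned with attribute \code{qualityFlag = TRUE}.
#' Calls of one or two pulses have no harmonic structure and return
#' \code{NA} (not an error).
#'
#' @param spec a [Spectrum-class] of the whole sound.
#' @param train the [PulseTrain-class] of the same sound.
#' @param searchRel half-width of the search window relative to the prior
#'   (default 0.35).
#' @return F0 in Hz (possibly with attribute \code{qualityFlag}), or NA for
#'   calls of fewer than three pulses.
#' @export
fundamentalFrequency <- function(spec, train, searchRel = 0.35) {
  stopifnot(is(spec, "Spectrum"), is(train, "PulseTrain"))
  np <- length(train@peakTimesMs)
  if (np < 3) return(NA_real_)
  prior <- 1000 / mean(diff(train@peakTimesMs))
  lo <- prior * (1 - searchRel)
  hi <- prior * (1 + searchRel)
  inWin <- spec@freqsHz >= lo & spec@freqsHz <= hi
  if (!any(inWin)) return(NA_real_)
  # whiten: divide by the local spectral baseline so the pulse-shape tilt
  # (power rising toward the resonance) does not drag the comb-line peak
  k <- max(3L, round(1.5 * prior / spec@resolutionHz))
  base <- movingAverage(spec@power, k)
  pw <- spec@power / pmax(base, max(spec@power) * 1e-12)
  f <- spec@freqsHz[inWin]
  p <- pw[inWin]
  f0 <- f[which.max(p)]
  if (abs(f0 - prior) / prior > 0.2) attr(f0, "qualityFlag") <- TRUE
  f0
}

#' Extract the per-sound acoustic variables
#'
#' Computes the standard call variables of one sound: total duration, pulse
#' count, mean pulse period (over all peak-to-peak periods, intervals
#' included), last-pulse duration, fundamental frequency, dominant frequency,
#' plus the pattern variables (mean interval, block count, mean pulses per
#' block) and the P1-P4 class. Variables that do not apply (e.g. period for a
#' single-pulse call, interval for a sound without pattern) are \code{NA},
#' never zero.
#'
#' @param w the conditioned [Waveform-class].
#' @param train the [PulseTrain-class] detected on \code{w}.
#' @param blocks the [BlockStructure-class] computed from the train's periods.
#' @param soundId,specimenId identifiers carried into the output row.
#' @return a one-row data.frame with columns \code{sound_id, specimen_id,
#'   duration_ms, n_pulses, period_ms, lastpulse_ms, f0_hz, fpeak_hz,
#'   interval_ms, n_blocks, pulses_per_block, p_class}.
#' @seealso [segmentBlocks()], [featureTable()]
#' @export
extractFeatures <- function(w, train, blocks,
                            soundId = NA_character_,
                            specimenId = NA_character_) {
  stopifnot(is(w, "Waveform"), is(train, "PulseTrain"),
            is(blocks, "BlockStructure"))
  np <- length(train@peakTimesMs)
  if (np == 0)
    hcStop("holocall_empty_train", "no pulses: nothing to extract")
  if (blocks@nPulses != np)
    hcStop("holocall_inconsistent_blocks",
           "block structure was computed for %d pulses but the train has %d",
           blocks@nPulses, np)
  periods <- diff(train@peakTimesMs)
  spec <- powerSpectrum(w)
  f0 <- fundamentalFrequency(spec, train)
  qual <- isTRUE(attr(f0, "qualityFlag"))
  f0 <- as.numeric(f0)
  if (!is.na(f0) && f0 > 220)
    hcWarn("fundamental frequency %.0f Hz exceeds the 220 Hz ceiling typical of holocentrid calls", f0)
  nb <- nrow(blocks@blockSpans)
  pat <- nb >= 2L
  data.frame(
    sound_id   = soundId,
    specimen_id = specimenId,
    duration_ms = train@soundOffsetMs - train@soundOnsetMs,
    n_pulses   = np,
    period_ms  = if (np >= 2) mean(periods) else NA_real_,
    lastpulse_ms = measureLastPulseDuration(w, train),
    f0_hz      = f0,
    fpeak_hz   = dominantFrequency(spec),
    interval_ms = if (pat) mean(blocks@intervalsMs) else NA_real_,
    n_blocks   = nb,
    pulses_per_block = mean(blocks@blockSpans[, 2] - blocks@blockSpans[, 1] + 1),
    p_class    = classifyPGroup(np, pat),
    f0_quality_flag = qual,
    stringsAsFactors = FALSE
  )
}

#' Write / read a per-sound feature table
#'
#' CSV contract: UTF-8, comma separated, header row, "." decimal; absent
#' values are empty cells, never 0 or -1. Round-trips preserve values to at
#' least 15 significant digits.
#'
#' @param features data.frame of rows from [extractFeatures()].
#' @param path CSV path.
#' @return \code{writeFeatureTable} the path invisibly;
#'   \code{readFeatureTable} the data.frame.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path))
    hcStop("holocall_missing_file", "file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
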