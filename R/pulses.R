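#' Detect pulses in a conditioned waveform
#'
#' Pulses are local maxima of the smoothed amplitude envelope (magnitude of
#' the analytic signal, 1 ms moving average) that exceed a relative threshold
#' and respect a refractory distance. This automates what is otherwise read
#' manually off the oscillogram: one peak per pulse, peak-to-peak differences
#' giving the pulse periods. Sound onset and offset are the first and last
#' crossings of 10 percent of the global envelope maximum.
#'
#' @param w a conditioned [Waveform-class].
#' @param minPeriodMs refractory distance between peaks (ms, default 4).
#' @param ampThresholdRel relative envelope threshold in (0, 1), default 0.2.
#' @param smoothMs envelope smoothing window (ms, default 1).
#' @return a [PulseTrain-class]; empty (zero pulses) on sub-threshold input.
#' @examples
#' tpl <- taxonTemplate("demo", f0Hz = c(100, 0), nPulses = c(7, 0))
#' call <- synthCall(tpl, seed = 1)
#' detectPulses(bandpassFilter(call$wave))
#' @export
detectPulses <- function(w, minPeriodMs = 4, ampThresholdRel = 0.2,
                         smoothMs = 1) {
  stopifnot(is(w, "Waveform"))
  if (!(ampThresholdRel > 0 && ampThresholdRel < 1))
    hcStop("holocall_bad_threshold",
           "ampThresholdRel must be in (0, 1), got %g", ampThresholdRel)
  env <- hilbertEnvelope(w@samples, w@rateHz, smoothMs = smoothMs)
  n <- length(env)
  emax <- max(env)
  thr <- ampThresholdRel * emax
  # sub-threshold input: the global max always equals the threshold bound,
  # so judge "signal present" against the envelope median (noise floor)
  if (emax < 6 * stats::median(env) || emax <= 0)
    return(new("PulseTrain", peakTimesMs = numeric(0),
               peakAmplitudes = numeric(0),
               soundOnsetMs = w@t0Ms, soundOffsetMs = w@t0Ms))

  minGap <- max(1L, as.integer(round(minPeriodMs / 1000 * w@rateHz)))
  # a pulse peak must come close to the envelope maximum within +/- the
  # refractory distance: ripple on a decaying tail sits well below the peak
  # that casts it, while a true peak is only undercut by the previous pulse's
  # immediate tail when periods barely exceed the refractory distance
  isMax <- c(FALSE, diff(env) > 0) & c(env[-n] >= env[-1], FALSE) & env > thr
  cand <- which(isMax)
  if (length(cand) == 0) cand <- which.max(env)
  cand <- cand[vapply(cand, function(i) {
    env[i] >= 0.75 * max(env[max(1L, i - minGap):min(n, i + minGap)])
  }, logical(1))]
  if (length(cand) == 0) cand <- which.max(env)
  # enforce the refractory distance, keeping the larger peak
  keep <- integer(0)
  for (i in cand[order(env[cand], decreasing = TRUE)]) {
    if (all(abs(keep - i) >= minGap)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  dtMs <- 1000 / w@rateHz
  # onset/offset: first/last crossing of 10% of the maximum, read on the
  # lightly smoothed rectified waveform -- causal, unlike the analytic
  # envelope, whose pre-ringing would push the onset early -- the way the
  # visible extent of a call is read off an oscillogram
  envb <- movingAverage(abs(w@samples), max(1L, round(0.0005 * w@rateHz)))
  above <- which(envb >= 0.1 * max(envb))
  new("PulseTrain",
      peakTimesMs    = w@t0Ms + (keep - 1) * dtMs,
      peakAmplitudes = env[keep],
      soundOnsetMs   = w@t0Ms + (above[1] - 1) * dtMs,
      soundOffsetMs  = w@t0Ms + (above[length(above)] - 1) * dtMs)
}

#' Estimate the signal-to-noise ratio of a recorded call
#'
#' Returns \code{10 log10(signal RMS^2 / noise RMS^2)}, where the signal is
#' measured inside the pulse spans (between sound onset and offset) and the
#' noise outside them (with a small guard margin). Invariant to global
#' amplitude scaling. Used to rank sounds for selection of the best-quality
#' recordings.
#'
#' @param w the [Waveform-class] the train was detected on.
#' @param train a non-empty [PulseTrain-class].
#' @param guardMs margin excluded on each side of the sound (ms, default 5).
#' @return SNR in dB.
#' @export
estimateSnr <- function(w, train, guardMs = 5) {
  stopifnot(is(w, "Waveform"), is(train, "PulseTrain"))
  if (length(train@peakTimesMs) == 0)
    hcStop("holocall_empty_train", "cannot estimate SNR on an empty pulse train")
  t <- timesMs(w)
  inSignal <- t >= train@soundOnsetMs & t <= train@soundOffsetMs
  inNoise  <- t < train@soundOnsetMs - guardMs | t > train@soundOffsetMs + guardMs
  if (sum(inNoise) < round(w@rateHz * 0.005))
    hcStop("holocall_no_noise_region",
           "no out-of-pulse region available to estimate the noise floor")
  ms <- function(x) mean(x^2)
  sig <- ms(w@samples[inSignal])
  noi <- ms(w@samples[inNoise])
  if (noi <= 0) return(Inf)
  10 * log10(max(sig - noi, .Machine$double.eps) / noi)
}

#' Select the best-quality sounds of one specimen
#'
#' Keeps the \code{k} sounds with the highest SNR (the recording protocol
#' keeps the 20 best of roughly 60 recorded per fish). Original order is
#' preserved within the subset; ties at the cut go to the lower index.
#'
#' @param snrDb numeric vector of per-sound SNR estimates (dB).
#' @param k number of sounds to keep (default 20).
#' @return integer indices of the selected sounds, in original order.
#' @examples
#' selectBestSounds(c(12, 30, 25, 30), k = 2)  # -> 2, 4
#' @export
selectBestSounds <- function(snrDb, k = 20) {
  if (length(snrDb) == 0)
    hcStop("holocall_empty_input", "no sounds to select from")
  stopifnot(k >= 1)
  if (length(snrDb) <= k) return(seq_along(snrDb))
  ord <- order(snrDb, seq_along(snrDb), decreasing = c(TRUE, FALSE),
               method = "radix")
  sort(ord[seq_len(k)])
}

#' Measure the duration of the last pulse
#'
#' The last pulse is the one whose duration can be read reliably, since no
#' later pulse masks its decay. Duration runs from the last-pulse envelope
#' onset (last crossing of \code{stopFraction} of its peak before the peak)
#' to the point where the envelope decays back below \code{stopFraction} of
#' that pulse's peak. For an exponential envelope with decay constant tau and
#' the default 10 percent criterion this is approximately \code{tau * ln 10}.
#'
#' @param w the [Waveform-class] the train was detected on.
#' @param train a non-empty [PulseTrain-class].
#' @param stopFraction envelope fraction ending the pulse (default 0.1).
#' @param riseFraction envelope fraction marking the pulse onset on the rise
#'   (default 0.5, the half-rise point -- sharp on an abrupt attack and
#'   robust to smoothing spread).
#' @param smoothMs envelope smoothing window (ms, default 1).
#' @return duration in ms.
#' @export
measureLastPulseDuration <- function(w, train, stopFraction = 0.1,
                                     riseFraction = 0.5, smoothMs = 1) {
  stopifnot(is(w, "Waveform"), is(train, "PulseTrain"))
  np <- length(train@peakTimesMs)
  if (np == 0)
    hcStop("holocall_empty_train", "cannot measure last pulse of an empty train")
  env <- hilbertEnvelope(w@samples, w@rateHz, smoothMs = smoothMs)
  floorAmp <- stats::median(env)
  env <- sqrt(pmax(env^2 - floorAmp^2, 0))  # noise-floor compensation
  t <- timesMs(w)
  iPeak <- which.min(abs(t - train@peakTimesMs[np]))
  # search window: from the previous peak (or signal start) to the end
  lo <- if (np > 1) which.min(abs(t - train@peakTimesMs[np - 1])) else 1L
  peakAmp <- env[iPeak]
  beforeBelow <- which(env[lo:iPeak] < riseFraction * peakAmp)
  # when the previous pulse's tail masks the rise, the onset is the envelope
  # valley between the two peaks
  iStart <- if (length(beforeBelow)) lo + max(beforeBelow) - 1L
            else lo + which.min(env[lo:iPeak]) - 1L
  afterBelow <- which(env[iPeak:length(env)] < stopFraction * peakAmp)
  iEnd <- if (length(afterBelow)) iPeak + min(afterBelow) - 1L else length(env)
  dur <- t[iEnd] - t[iStart]
  max(dur, 1000 / w@rateHz)
}
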