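#' @import methods
NULL

#' Waveform: a mono audio signal
#'
#' Container for one mono waveform. Amplitudes are dimensionless in
#' \code{[-1, 1]}; all times in the package are milliseconds and all
#' frequencies Hz. The canonical internal rate is 44100 Hz.
#'
#' @slot samples numeric vector of amplitudes in \code{[-1, 1]}.
#' @slot rateHz sampling rate in Hz.
#' @slot t0Ms time origin of the first sample, in ms.
#'
#' @seealso [readWav()], [bandpassFilter()], [detectPulses()]
#' @export
setClass("Waveform", representation(
  samples = "numeric",
  rateHz  = "numeric",
  t0Ms    = "numeric"
))

setValidity("Waveform", function(object) {
  msg <- NULL
  if (length(object@samples) == 0L) msg <- c(msg, "samples must be non-empty")
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (length(object@t0Ms) != 1L || !is.finite(object@t0Ms))
    msg <- c(msg, "t0Ms must be a single finite number")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (is.null(msg)) TRUE else msg
})

#' PulseTrain: detected pulses of one sound
#'
#' Pulse peak times and amplitudes for a single call, together with the
#' envelope-based sound onset and offset. Pulse periods (peak-to-peak
#' differences, the quantity read off oscillograms) are available through
#' [periodsMs()].
#'
#' @slot peakTimesMs strictly increasing pulse peak times (ms).
#' @slot peakAmplitudes envelope amplitude at each peak.
#' @slot soundOnsetMs envelope-based sound onset (ms).
#' @slot soundOffsetMs envelope-based sound offset (ms).
#'
#' @export
setClass("PulseTrain", representation(
  peakTimesMs    = "numeric",
  peakAmplitudes = "numeric",
  soundOnsetMs   = "numeric",
  soundOffsetMs  = "numeric"
))

setValidity("PulseTrain", function(object) {
  msg <- NULL
  n <- length(object@peakTimesMs)
  if (length(object@peakAmplitudes) != n)
    msg <- c(msg, "peakTimesMs and peakAmplitudes must have equal length")
  if (n > 1 && any(diff(object@peakTimesMs) <= 0))
    msg <- c(msg, "peakTimesMs must be strictly increasing")
  if (n > 0) {
    if (object@soundOnsetMs > object@peakTimesMs[1] + 1e-9)
      msg <- c(msg, "soundOnsetMs must not exceed the first peak time")
    if (object@soundOffsetMs < object@peakTimesMs[n] - 1e-9)
      msg <- c(msg, "soundOffsetMs must not precede the last peak time")
  }
  if (is.null(msg)) TRUE else msg
})

#' Spectrum: power spectrum of a whole sound
#'
#' Single-window power spectrum with the frequency resolution the analysis
#' requires (zero padding brings bin spacing to ~5 Hz or finer regardless of
#' call duration).
#'
#' @slot freqsHz frequency grid (Hz).
#' @slot power non-negative power per bin.
#' @slot resolutionHz bin spacing (Hz), at most 5.5.
#'
#' @export
setClass("Spectrum", representation(
  freqsHz      = "numeric",
  power        = "numeric",
  resolutionHz = "numeric"
))

setValidity("Spectrum", function(object) {
  msg <- NULL
  if (length(object@freqsHz) != length(object@power))
    msg <- c(msg, "freqsHz and power must have equal length")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(object@resolutionHz) != 1L || object@resolutionHz <= 0 ||
      object@resolutionHz > 5.5)
    msg <- c(msg, "resolutionHz must be positive and at most 5.5 Hz")
  if (is.null(msg)) TRUE else msg
})

#' BlockStructure: block segmentation of a pulse train
#'
#' Result of the interval rule: a period is an interval when it exceeds
#' \code{ratio} times the mean pulse period (the last period never counts,
#' and sounds of three or fewer pulses are a single block without pattern).
#' Blocks are the maximal runs of pulses between intervals.
#'
#' @slot blockSpans integer matrix, one row per block, columns
#'   \code{first}/\code{last}: 0-based inclusive pulse indices.
#' @slot intervalsMs the periods classified as intervals (ms).
#' @slot ratioUsed the threshold multiplier applied.
#' @slot nPulses pulse count of the segmented sound.
#'
#' @export
setClass("BlockStructure", representation(
  blockSpans  = "matrix",
  intervalsMs = "numeric",
  ratioUsed   = "numeric",
  nPulses     = "integer"
))

setValidity("BlockStructure", function(object) {
  msg <- NULL
  sp <- object@blockSpans
  if (ncol(sp) != 2L) msg <- c(msg, "blockSpans must have two columns")
  if (nrow(sp) != length(object@intervalsMs) + 1L)
    msg <- c(msg, "n_blocks must equal number of intervals + 1")
  if (nrow(sp) >= 1L) {
    if (sp[1, 1] != 0L || sp[nrow(sp), 2] != object@nPulses - 1L)
      msg <- c(msg, "blocks must span pulses 0 .. nPulses-1")
    if (nrow(sp) > 1L && any(sp[-1, 1] != sp[-nrow(sp), 2] + 1L))
      msg <- c(msg, "blocks must be contiguous and ordered")
  }
  if (object@nPulses <= 3L && nrow(sp) > 1L)
    msg <- c(msg, "sounds of <= 3 pulses are a single block")
  if (is.null(msg)) TRUE else msg
})

#' AcousticSpace: standardized PCA of individual call summaries
#'
#' Correlation-matrix PCA of per-individual acoustic variables, with the
#' number of retained components set by the eigenvalue-greater-than-one rule.
#'
#' @slot scores individuals x PC score matrix.
#' @slot loadings variables x PC loading (rotation) matrix, orthonormal.
#' @slot varExplained percent variance per PC (sums to 100).
#' @slot retained number of PCs with eigenvalue > 1.
#' @slot variableSet names of the variables used.
#'
#' @export
setClass("AcousticSpace", representation(
  scores       = "matrix",
  loadings     = "matrix",
  varExplained = "numeric",
  retained     = "integer",
  variableSet  = "character"
))

setValidity("AcousticSpace", function(object) {
  msg <- NULL
  if (abs(sum(object@varExplained) - 100) > 1e-6)
    msg <- c(msg, "varExplained must sum to 100")
  if (object@retained < 1L) msg <- c(msg, "retained must be >= 1")
  cross <- crossprod(object@loadings)
  if (max(abs(cross - diag(ncol(object@loadings)))) > 1e-6)
    msg <- c(msg, "loadings must be orthonormal")
  if (is.null(msg)) TRUE else msg
})

#' ClassificationReport: discriminant classification of individuals
#'
#' Correct classification rate (CCR), per-class CCR, and the
#' conditional-frequency confusion matrix (rows are true classes and sum
#' to one) for one taxonomic grouping.
#'
#' @slot level name of the taxonomic grouping.
#' @slot method discriminant flavor used ("fda" or "lda").
#' @slot nTotal number of classified individuals.
#' @slot nCorrect number correctly classified.
#' @slot perClassCCR named per-class correct classification rates.
#' @slot confusion conditional-frequency confusion matrix.
#' @slot truth true class labels.
#' @slot assigned assigned class labels.
#'
#' @export
setClass("ClassificationReport", representation(
  level       = "character",
  method      = "character",
  nTotal      = "integer",
  nCorrect    = "integer",
  perClassCCR = "numeric",
  confusion   = "matrix",
  truth       = "factor",
  assigned    = "factor"
))

setValidity("ClassificationReport", function(object) {
  msg <- NULL
  if (object@nCorrect > object@nTotal) msg <- c(msg, "nCorrect exceeds nTotal")
  rs <- rowSums(object@confusion)
  if (any(abs(rs - 1) > 1e-9)) msg <- c(msg, "confusion rows must sum to 1")
  d <- diag(object@confusion)
  if (max(abs(d - object@perClassCCR[rownames(object@confusion)])) > 1e-9)
    msg <- c(msg, "confusion diagonal must equal perClassCCR")
  if (is.null(msg)) TRUE else msg
})

#' TaxonTemplate: generative model of one taxon's calls
#'
#' Parameters of the synthetic-call generator for one taxon. Distributional
#' slots are length-2 numeric vectors \code{c(mean, sd)}; draws are from
#' truncated normals with physical bounds. The fundamental frequency is drawn
#' and the pulse period follows deterministically as \code{1000 / F0}
#' (contraction rate of the sonic muscles sets both), keeping F0 at or below
#' the 220 Hz ceiling observed across holocentrids.
#'
#' @slot name taxon label.
#' @slot durationMs c(mean, sd) of the call duration (ms), or c(NA, NA).
#'   When given, the pulse count of each call is derived from the drawn
#'   duration, period and block layout (slow-period calls then carry fewer
#'   pulses, as observed across taxa); when NA, the pulse count is drawn
#'   from \code{nPulses} and the duration emerges.
#' @slot nPulses c(mean, sd) of the pulse count (min 1, rounded).
#' @slot f0Hz c(mean, sd) of the fundamental frequency (Hz), truncated to
#'   \code{[f0Bounds]}.
#' @slot f0Bounds c(lo, hi) truncation bounds for F0 (hi at most 220).
#' @slot resonanceHz c(mean, sd) of the pulse resonant (dominant) frequency.
#' @slot lastPulseTauMs exponential decay constant of each pulse envelope;
#'   a 10-percent stop criterion reads ~tau*ln(10) ms as the pulse duration.
#' @slot patternProb probability a call is emitted with pattern (>= 2 blocks).
#' @slot nBlocks c(mean, sd) of the block count given pattern (min 2).
#' @slot intervalMs c(mean, sd) of between-block intervals (ms); enforced
#'   above 1.25x the call's mean period so the rule can recover the blocks.
#' @slot tlMm c(mean, sd) of specimen total length (mm).
#' @slot tlSlopes named list of per-variable slopes of X on TL
#'   (supported names: duration_ms, f0_hz, fpeak_hz, lastpulse_ms, n_pulses).
#' @slot snrDb signal-to-noise ratio of emitted calls (dB).
#'
#' @seealso [taxonTemplate()], [holocentridTemplates()], [synthCall()]
#' @export
setClass("TaxonTemplate", representation(
  name           = "character",
  durationMs     = "numeric",
  nPulses        = "numeric",
  f0Hz           = "numeric",
  f0Bounds       = "numeric",
  resonanceHz    = "numeric",
  lastPulseTauMs = "numeric",
  patternProb    = "numeric",
  nBlocks        = "numeric",
  intervalMs     = "numeric",
  tlMm           = "numeric",
  tlSlopes       = "list",
  snrDb          = "numeric"
))

setValidity("TaxonTemplate", function(object) {
  msg <- NULL
  two <- function(x) length(x) == 2L && all(is.finite(x)) && x[2] >= 0
  if (!two(object@nPulses) || object@nPulses[1] < 1)
    msg <- c(msg, "nPulses must be c(mean >= 1, sd >= 0)")
  if (length(object@durationMs) != 2L ||
      (!all(is.na(object@durationMs)) &&
       (any(!is.finite(object@durationMs)) || object@durationMs[1] <= 0 ||
        object@durationMs[2] < 0)))
    msg <- c(msg, "durationMs must be c(mean > 0, sd >= 0) or c(NA, NA)")
  if (!two(object@f0Hz) || object@f0Hz[1] <= 0)
    msg <- c(msg, "f0Hz must be c(mean > 0, sd >= 0)")
  if (length(object@f0Bounds) != 2L || object@f0Bounds[1] <= 0 ||
      object@f0Bounds[2] > 220 || object@f0Bounds[1] >= object@f0Bounds[2])
    msg <- c(msg, "f0Bounds must be 0 < lo < hi <= 220")
  if (!two(object@resonanceHz) || object@resonanceHz[1] <= 0)
    msg <- c(msg, "resonanceHz must be c(mean > 0, sd >= 0)")
  if (object@lastPulseTauMs <= 0) msg <- c(msg, "lastPulseTauMs must be > 0")
  if (object@patternProb < 0 || object@patternProb > 1)
    msg <- c(msg, "patternProb must lie in [0, 1]")
  if (!two(object@nBlocks) || object@nBlocks[1] < 2)
    msg <- c(msg, "nBlocks must be c(mean >= 2, sd >= 0)")
  if (!two(object@intervalMs) || object@intervalMs[1] <= 0)
    msg <- c(msg, "intervalMs must be c(mean > 0, sd >= 0)")
  if (object@patternProb > 0 &&
      object@intervalMs[1] <= 1000 / object@f0Hz[1])
    msg <- c(msg, "infeasible template: interval must exceed the mean period")
  if (!two(object@tlMm) || object@tlMm[1] <= 0)
    msg <- c(msg, "tlMm must be c(mean > 0, sd >= 0)")
  if (is.null(msg)) TRUE else msg
})
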