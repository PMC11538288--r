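#' Accessors for Waveform
#'
#' @param x a [Waveform-class] object.
#' @return \code{samples()} the amplitude vector; \code{rateHz()} the
#'   sampling rate; \code{durationMs()} the total duration in ms.
#' @name waveform-accessors
#' @aliases samples rateHz durationMs
NULL

#' @rdname waveform-accessors
#' @export
setMethod("samples", "Waveform", function(x) x@samples)

#' @rdname waveform-accessors
#' @export
setMethod("rateHz", "Waveform", function(x) x@rateHz)

#' @rdname waveform-accessors
#' @export
setMethod("durationMs", "Waveform",
          function(x) length(x@samples) / x@rateHz * 1000)

#' Time axis of a waveform
#'
#' @param w a [Waveform-class].
#' @return sample times in ms, starting at the waveform's time origin.
#' @export
timesMs <- function(w) {
  stopifnot(is(w, "Waveform"))
  w@t0Ms + (seq_along(w@samples) - 1) / w@rateHz * 1000
}

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.1f ms), range [%.3f, %.3f]\n",
              length(object@samples), object@rateHz, durationMs(object),
              min(object@samples), max(object@samples)))
})

#' Accessors for PulseTrain
#'
#' @param x a [PulseTrain-class] object.
#' @return \code{peakTimesMs()} pulse peak times (ms); \code{peakAmplitudes()}
#'   envelope amplitude at each peak; \code{nPulses()} the pulse count;
#'   \code{periodsMs()} the peak-to-peak pulse periods (length nPulses - 1).
#' @name pulsetrain-accessors
#' @aliases peakTimesMs peakAmplitudes nPulses,PulseTrain-method periodsMs
NULL

#' @rdname pulsetrain-accessors
#' @export
setMethod("peakTimesMs", "PulseTrain", function(x) x@peakTimesMs)

#' @rdname pulsetrain-accessors
#' @export
setMethod("peakAmplitudes", "PulseTrain", function(x) x@peakAmplitudes)

#' @rdname pulsetrain-accessors
#' @export
setMethod("nPulses", "PulseTrain", function(x) length(x@peakTimesMs))

#' @rdname pulsetrain-accessors
#' @export
setMethod("periodsMs", "PulseTrain", function(x) diff(x@peakTimesMs))

#' Sound onset and offset
#'
#' Envelope-based boundaries of the sound: first and last crossing of 10
#' percent of the global envelope maximum.
#'
#' @param train a [PulseTrain-class].
#' @return onset or offset time in ms.
#' @export
soundOnsetMs <- function(train) train@soundOnsetMs

#' @rdname soundOnsetMs
#' @export
soundOffsetMs <- function(train) train@soundOffsetMs

setMethod("show", "PulseTrain", function(object) {
  n <- length(object@peakTimesMs)
  cat(sprintf("PulseTrain: %d pulse%s", n, if (n == 1) "" else "s"))
  if (n > 1)
    cat(sprintf(", mean period %.2f ms", mean(diff(object@peakTimesMs))))
  cat(sprintf(", sound %.1f-%.1f ms\n",
              object@soundOnsetMs, object@soundOffsetMs))
})

#' Accessors for Spectrum
#'
#' @param x a [Spectrum-class] object.
#' @return \code{freqsHz()} the frequency grid; \code{spectralPower()} the
#'   power per bin; \code{resolutionHz()} the bin spacing.
#' @name spectrum-accessors
#' @aliases freqsHz spectralPower resolutionHz
NULL

#' @rdname spectrum-accessors
#' @export
setMethod("freqsHz", "Spectrum", function(x) x@freqsHz)

#' @rdname spectrum-accessors
#' @export
setMethod("spectralPower", "Spectrum", function(x) x@power)

#' @rdname spectrum-accessors
#' @export
setMethod("resolutionHz", "Spectrum", function(x) x@resolutionHz)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bins, %.2f-%.0f Hz, resolution %.2f Hz\n",
              length(object@freqsHz), min(object@freqsHz),
              max(object@freqsHz), object@resolutionHz))
})

#' Accessors for BlockStructure
#'
#' @param x a [BlockStructure-class] object.
#' @return \code{blockSpans()} 0-based inclusive pulse-index spans (matrix);
#'   \code{intervalsMs()} the periods classified as intervals;
#'   \code{nBlocks()} the block count; \code{hasPattern()} TRUE when the
#'   sound has two or more blocks.
#' @name blockstructure-accessors
#' @aliases blockSpans intervalsMs nBlocks hasPattern
NULL

#' @rdname blockstructure-accessors
#' @export
setMethod("blockSpans", "BlockStructure", function(x) x@blockSpans)

#' @rdname blockstructure-accessors
#' @export
setMethod("intervalsMs", "BlockStructure", function(x) x@intervalsMs)

#' @rdname blockstructure-accessors
#' @export
setMethod("nBlocks", "BlockStructure", function(x) nrow(x@blockSpans))

#' @rdname blockstructure-accessors
#' @export
setMethod("hasPattern", "BlockStructure", function(x) nrow(x@blockSpans) >= 2L)

#' @rdname blockstructure-accessors
#' @export
setMethod("nPulses", "BlockStructure", function(x) as.integer(x@nPulses))

setMethod("show", "BlockStructure", function(object) {
  nb <- nrow(object@blockSpans)
  cat(sprintf("BlockStructure: %d pulse%s in %d block%s (%s pattern, ratio %.2f)\n",
              object@nPulses, if (object@nPulses == 1) "" else "s",
              nb, if (nb == 1) "" else "s",
              if (nb >= 2) "with" else "no", object@ratioUsed))
})

#' Accessors for AcousticSpace
#'
#' @param x an [AcousticSpace-class] object.
#' @return \code{pcScores()} per-individual PC coordinates;
#'   \code{pcLoadings()} the variable loadings; \code{varExplained()} percent
#'   variance per PC; \code{nRetained()} PCs with eigenvalue above one.
#' @name acousticspace-accessors
#' @aliases pcScores pcLoadings varExplained nRetained
NULL

#' @rdname acousticspace-accessors
#' @export
setMethod("pcScores", "AcousticSpace", function(x) x@scores)

#' @rdname acousticspace-accessors
#' @export
setMethod("pcLoadings", "AcousticSpace", function(x) x@loadings)

#' @rdname acousticspace-accessors
#' @export
setMethod("varExplained", "AcousticSpace", function(x) x@varExplained)

#' @rdname acousticspace-accessors
#' @export
setMethod("nRetained", "AcousticSpace", function(x) x@retained)

setMethod("show", "AcousticSpace", function(object) {
  cat(sprintf("AcousticSpace: %d individuals x %d variables (%s)\n",
              nrow(object@scores), length(object@variableSet),
              paste(object@variableSet, collapse = ", ")))
  ve <- object@varExplained
  cat(sprintf("  PC1-%d explain %s%% (cumulative %.0f%%); %d PC%s retained (eigenvalue > 1)\n",
              min(3, length(ve)),
              paste(sprintf("%.0f", ve[seq_len(min(3, length(ve)))]), collapse = ", "),
              sum(ve[seq_len(min(3, length(ve)))]),
              object@retained, if (object@retained == 1) "" else "s"))
})

#' Accessors for ClassificationReport
#'
#' @param x a [ClassificationReport-class] object.
#' @return \code{ccr()} the overall correct classification rate in
#'   \code{[0, 1]}; \code{perClassCCR()} per-class rates;
#'   \code{confusionMatrix()} the conditional-frequency confusion matrix
#'   (rows are true classes and sum to one); \code{assignedClasses()} the
#'   assigned labels.
#' @name classificationreport-accessors
#' @aliases ccr perClassCCR confusionMatrix assignedClasses
NULL

#' @rdname classificationreport-accessors
#' @export
setMethod("ccr", "ClassificationReport",
          function(x) x@nCorrect / x@nTotal)

#' @rdname classificationreport-accessors
#' @export
setMethod("perClassCCR", "ClassificationReport", function(x) x@perClassCCR)

#' @rdname classificationreport-accessors
#' @export
setMethod("confusionMatrix", "ClassificationReport", function(x) x@confusion)

#' @rdname classificationreport-accessors
#' @export
setMethod("assignedClasses", "ClassificationReport", function(x) x@assigned)

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport (%s, %s): CCR %.0f%% (%d out of %d)\n",
              object@level, object@method,
              100 * object@nCorrect / object@nTotal,
              object@nCorrect, object@nTotal))
  pc <- sort(object@perClassCCR, decreasing = TRUE)
  cat("  per-class CCR: ",
      paste(sprintf("%s %.1f%%", names(pc), 100 * pc), collapse = "; "),
      "\n", sep = "")
})

setMethod("show", "TaxonTemplate", function(object) {
  cat(sprintf("TaxonTemplate '%s': F0 %g +/- %g Hz, %g +/- %g pulses,\n",
              object@name, object@f0Hz[1], object@f0Hz[2],
              object@nPulses[1], object@nPulses[2]))
  cat(sprintf("  resonance %g +/- %g Hz, pulse tau %g ms, pattern prob %.2f, SNR %g dB\n",
              object@resonanceHz[1], object@resonanceHz[2],
              object@lastPulseTauMs, object@patternProb, object@snrDb))
})
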