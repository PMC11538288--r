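# Generics for the package's accessor layer. Methods live next to the
# classes they serve.

#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))
#' @export
setGeneric("durationMs", function(x) standardGeneric("durationMs"))
#' @export
setGeneric("peakTimesMs", function(x) standardGeneric("peakTimesMs"))
#' @export
setGeneric("peakAmplitudes", function(x) standardGeneric("peakAmplitudes"))
#' @export
setGeneric("nPulses", function(x) standardGeneric("nPulses"))
#' @export
setGeneric("periodsMs", function(x) standardGeneric("periodsMs"))
#' @export
setGeneric("freqsHz", function(x) standardGeneric("freqsHz"))
#' @export
setGeneric("spectralPower", function(x) standardGeneric("spectralPower"))
#' @export
setGeneric("resolutionHz", function(x) standardGeneric("resolutionHz"))
#' @export
setGeneric("blockSpans", function(x) standardGeneric("blockSpans"))
#' @export
setGeneric("intervalsMs", function(x) standardGeneric("intervalsMs"))
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))
#' @export
setGeneric("hasPattern", function(x) standardGeneric("hasPattern"))
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))
#' @export
setGeneric("ccr", function(x) standardGeneric("ccr"))
#' @export
setGeneric("perClassCCR", function(x) standardGeneric("perClassCCR"))
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @export
setGeneric("assignedClasses", function(x) standardGeneric("assignedClasses"))
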