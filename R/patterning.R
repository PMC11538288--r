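#' Segment a pulse train into blocks by the interval rule
#'
#' A peak-to-peak period is classified as an interval (a gap between blocks)
#' when it exceeds \code{ratio} times the mean pulse period of the sound,
#' where the mean is taken over all periods of the sound (intervals
#' included). Two qualifications, both part of the rule: the last period is
#' never an interval even when it meets the criterion, and sounds of three or
#' fewer pulses are a single block, automatically without pattern. Blocks are
#' the maximal runs of pulses between intervals. The rule is scale-free:
#' multiplying all periods by a constant leaves the segmentation unchanged.
#'
#' @param periodsMs positive peak-to-peak periods of one sound (ms); length
#'   \code{nPulses - 1}. An empty vector is a single-pulse sound.
#' @param ratio threshold multiplier (> 1), default 1.25, the value that best
#'   aligns computed block counts with visual counts (see
#'   [calibrateIntervalRatio()]).
#' @return a [BlockStructure-class].
#' @examples
#' segmentBlocks(c(10, 10, 25, 10, 10))  # 2 blocks of 3 pulses
#' segmentBlocks(c(10, 10, 10, 25))      # 1 block: last period never counts
#' @export
segmentBlocks <- function(periodsMs, ratio = 1.25) {
  if (length(periodsMs) > 0 && any(periodsMs <= 0))
    hcStop("holocall_bad_periods", "periods must all be positive")
  if (ratio <= 1)
    hcStop("holocall_bad_ratio", "ratio must exceed 1, got %g", ratio)
  np <- length(periodsMs) + 1L
  isInterval <- rep(FALSE, length(periodsMs))
  if (np > 3L) {
    thr <- ratio * mean(periodsMs)
    isInterval <- periodsMs > thr
    isInterval[length(isInterval)] <- FALSE  # last period never an interval
  }
  cut <- which(isInterval)          # period i separates pulses i-1 and i (0-based)
  first <- c(0L, cut)
  last  <- c(cut - 1L, np - 1L)
  new("BlockStructure",
      blockSpans = cbind(first = as.integer(first), last = as.integer(last)),
      intervalsMs = periodsMs[cut],
      ratioUsed = ratio,
      nPulses = np)
}

#' Classify a sound into the P1-P4 groups
#'
#' P1: one pulse. P2: two pulses. P3: more than two pulses, no pattern.
#' P4: more than three pulses distributed in blocks (with pattern). The four
#' groups partition any corpus.
#'
#' @param nPulses pulse count (>= 1).
#' @param hasPattern logical; must be FALSE when \code{nPulses <= 3}.
#' @return one of \code{"P1"}, \code{"P2"}, \code{"P3"}, \code{"P4"}.
#' @examples
#' classifyPGroup(7, FALSE)  # "P3"
#' classifyPGroup(6, TRUE)   # "P4"
#' @export
classifyPGroup <- function(nPulses, hasPattern) {
  stopifnot(length(nPulses) == 1L, length(hasPattern) == 1L)
  if (nPulses < 1)
    hcStop("holocall_bad_pulse_count", "nPulses must be >= 1, got %g", nPulses)
  if (nPulses <= 3 && hasPattern)
    hcStop("holocall_inconsistent_pattern",
           "a sound of %d pulse(s) cannot have pattern", nPulses)
  if (nPulses == 1) "P1"
  else if (nPulses == 2) "P2"
  else if (!hasPattern) "P3"
  else "P4"
}

#' Calibrate the interval threshold against visually annotated sounds
#'
#' Given candidate multipliers and sounds annotated with visually observed
#' block counts, returns the candidate whose computed block counts disagree
#' with the annotations for the fewest sounds. Ties break toward the smallest
#' candidate. The per-candidate agreement table is attached as attribute
#' \code{"agreement"}. With candidates (1.15, 1.20, 1.25, 1.30, 1.35, 1.40)
#' and a representative annotated sample, this procedure selects 1.25.
#'
#' @param candidates numeric vector of threshold multipliers (> 1).
#' @param annotated list of sounds, each a list with elements
#'   \code{periods_ms} (numeric) and \code{visual_block_count} (integer).
#' @return the selected multiplier, with attribute \code{"agreement"}: a
#'   data.frame of candidate, n_agree, n_total.
#' @seealso [segmentBlocks()]
#' @export
calibrateIntervalRatio <- function(candidates = c(1.15, 1.20, 1.25, 1.30, 1.35, 1.40),
                                   annotated) {
  if (length(candidates) == 0)
    hcStop("holocall_empty_input", "no candidate ratios supplied")
  if (missing(annotated) || length(annotated) == 0)
    hcStop("holocall_empty_input", "no annotated sounds supplied")
  nAgree <- vapply(candidates, function(r) {
    sum(vapply(annotated, function(s) {
      nBlocks(segmentBlocks(s$periods_ms, ratio = r)) == s$visual_block_count
    }, logical(1)))
  }, numeric(1))
  best <- candidates[order(-nAgree, candidates)][1]
  attr(best, "agreement") <- data.frame(candidate = candidates,
                                        n_agree = nAgree,
                                        n_total = length(annotated))
  best
}

#' Percentage of sounds with pattern
#'
#' Per-individual variable 10: the percentage of an individual's analyzed
#' sounds that show a pattern (two or more blocks).
#'
#' @param x logical vector, one element per sound (or a list of
#'   [BlockStructure-class] objects).
#' @return percentage in \code{[0, 100]}.
#' @export
patternPercentage <- function(x) {
  if (is.list(x)) x <- vapply(x, hasPattern, logical(1))
  if (length(x) == 0)
    hcStop("holocall_empty_input", "no sounds: pattern percentage undefined")
  100 * mean(as.logical(x))
}
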