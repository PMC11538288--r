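# Per-individual layer: individuals, not sounds, are the unit of the
# comparative analyses.

.genusSubfamily <- c(Myripristis = "Myripristinae",
                     Flammeo = "Holocentrinae",
                     Holocentrus = "Holocentrinae",
                     Sargocentron = "Holocentrinae",
                     Neoniphon = "Holocentrinae")

# the four size-linked variables, divided by TL before comparative analyses
.sizeLinkedVars <- c("duration_ms", "n_pulses", "lastpulse_ms", "fpeak_hz")

#' Subfamily of a holocentrid genus
#'
#' Total, consistent mapping for the five genera in scope: Myripristis is
#' Myripristinae; Flammeo, Holocentrus, Sargocentron and Neoniphon are
#' Holocentrinae.
#'
#' @param genus character vector of genus names.
#' @return character vector of subfamilies.
#' @export
genusToSubfamily <- function(genus) {
  out <- unname(.genusSubfamily[genus])
  if (any(is.na(out) & !is.na(genus)))
    hcStop("holocall_unknown_genus", "unknown genus: %s",
           paste(unique(genus[is.na(out) & !is.na(genus)]), collapse = ", "))
  out
}

#' Read and validate a specimen metadata table
#'
#' Expected columns: \code{specimen_id, species, genus, subfamily, group,
#' TL_mm, SL_mm, site} (SL_mm, site optional). Subfamily is checked against
#' the genus; \code{group} is the Myripristis subgroup (1, 2 or empty).
#'
#' @param path CSV path.
#' @return data.frame of specimens.
#' @export
readSpecimens <- function(path) {
  if (!file.exists(path))
    hcStop("holocall_missing_file", "specimen metadata not found: %s", path)
  sp <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("specimen_id", "species", "genus", "subfamily", "TL_mm")
  miss <- setdiff(need, names(sp))
  if (length(miss))
    hcStop("holocall_bad_metadata", "specimen table lacks columns: %s",
           paste(miss, collapse = ", "))
  known <- sp$genus %in% names(.genusSubfamily)
  expect <- rep(NA_character_, nrow(sp))
  expect[known] <- unname(.genusSubfamily[sp$genus[known]])
  bad <- known & !is.na(sp$subfamily) & sp$subfamily != expect
  if (any(bad))
    hcStop("holocall_bad_metadata",
           "subfamily inconsistent with genus for: %s",
           paste(sp$specimen_id[bad], collapse = ", "))
  if (any(!is.na(sp$TL_mm) & sp$TL_mm <= 0))
    hcStop("holocall_bad_tl", "TL_mm must be positive where present")
  sp
}

#' Summarize one individual's analyzed sounds
#'
#' Per-variable mean over the sounds where the variable is defined, plus the
#' percentage of sounds with pattern (variable 10) and the sound count. The
#' summary is invariant to the order of the sounds.
#'
#' @param features data.frame of per-sound rows ([extractFeatures()] format)
#'   for one specimen.
#' @return a one-row data.frame: \code{specimen_id}, per-variable means,
#'   \code{pct_pattern}, \code{n_sounds}.
#' @export
summarizeIndividual <- function(features) {
  if (nrow(features) == 0)
    hcStop("holocall_empty_input", "no sounds for this specimen")
  if (length(unique(features$specimen_id)) > 1)
    hcStop("holocall_bad_metadata", "features of more than one specimen supplied")
  meanDef <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  vars <- c("duration_ms", "n_pulses", "period_ms", "lastpulse_ms",
            "f0_hz", "fpeak_hz", "interval_ms", "n_blocks", "pulses_per_block")
  out <- as.data.frame(lapply(features[vars], meanDef))
  cbind(data.frame(specimen_id = features$specimen_id[1],
                   stringsAsFactors = FALSE),
        out,
        data.frame(pct_pattern = 100 * mean(features$n_blocks >= 2),
                   n_sounds = nrow(features)))
}

#' Summarize all individuals of a feature table
#'
#' @param features per-sound feature data.frame (several specimens).
#' @param specimens specimen metadata data.frame (see [readSpecimens()]);
#'   joined onto the summaries when supplied.
#' @return data.frame, one row per specimen.
#' @export
summarizeIndividuals <- function(features, specimens = NULL) {
  rows <- lapply(split(features, features$specimen_id), summarizeIndividual)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(specimens))
    out <- merge(specimens, out, by = "specimen_id", sort = TRUE)
  out
}

#' Per-species regressions of acoustic variables on body size
#'
#' Ordinary least-squares fit of each variable on total length (TL), one fit
#' per species with at least \code{minN} individuals; smaller species are
#' skipped with a warning. The candidate size-linked set is duration, pulse
#' count, last-pulse duration and dominant frequency.
#'
#' @param summaries individual-summary data.frame with \code{species} and
#'   \code{TL_mm} columns.
#' @param variables variable names to regress (default the size-linked set).
#' @param minN minimum individuals per species (default 3).
#' @return data.frame: species, variable, slope, intercept, p_value,
#'   r_squared, n.
#' @export
fitSizeRegressions <- function(summaries, variables = .sizeLinkedVars,
                               minN = 3) {
  if (!"TL_mm" %in% names(summaries))
    hcStop("holocall_bad_metadata", "summaries lack a TL_mm column")
  res <- list()
  for (spc in unique(summaries$species)) {
    d <- summaries[summaries$species == spc & !is.na(summaries$TL_mm), ]
    for (v in variables) {
      dv <- d[!is.na(d[[v]]), ]
      if (nrow(dv) < minN) {
        hcWarn("species %s skipped for %s (n = %d < %d)", spc, v, nrow(dv), minN)
        next
      }
      fit <- stats::lm(dv[[v]] ~ dv$TL_mm)
      sm <- summary(fit)
      pv <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        species = spc, variable = v,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        p_value = pv, r_squared = sm$r.squared, n = nrow(dv),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    hcStop("holocall_empty_input",
           "no species with enough individuals for a regression")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Remove the body-size effect: X(TL)^-1 normalization
#'
#' Divides each size-linked variable by the specimen's total length
#' (X becomes X/TL, units per mm). Rows lacking TL are dropped from the
#' returned table (mirroring the exclusion of specimens without size
#' measurements from the comparative analyses) and the count is reported.
#' Because TL is constant within an individual, normalizing per sound and
#' then averaging equals normalizing the individual means.
#'
#' @param table data.frame with a \code{TL_mm} column (per-sound or
#'   per-individual).
#' @param variables names to normalize (default the size-linked set:
#'   duration, pulse count, last-pulse duration, dominant frequency).
#' @return the table with normalized columns and rows lacking TL removed;
#'   attribute \code{"n_dropped"} carries the exclusion count.
#' @export
normalizeByLength <- function(table, variables = .sizeLinkedVars) {
  if (!"TL_mm" %in% names(table))
    hcStop("holocall_bad_metadata", "table lacks a TL_mm column")
  if (any(!is.na(table$TL_mm) & table$TL_mm <= 0))
    hcStop("holocall_bad_tl", "TL_mm must be positive")
  keep <- !is.na(table$TL_mm)
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(nDropped, " row(s) without TL excluded from comparative analyses")
  out <- table[keep, , drop = FALSE]
  for (v in intersect(variables, names(out)))
    out[[v]] <- out[[v]] / out$TL_mm
  attr(out, "n_dropped") <- nDropped
  out
}

#' The size-linked variable set
#'
#' @return names of the four variables divided by TL before comparative
#'   analyses.
#' @export
sizeLinkedVariables <- function() .sizeLinkedVars
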