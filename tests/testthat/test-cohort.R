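test_that("genus-to-subfamily mapping is total and consistent", {
  expect_equal(genusToSubfamily("Myripristis"), "Myripristinae")
  expect_equal(genusToSubfamily(c("Flammeo", "Holocentrus", "Sargocentron",
                                  "Neoniphon")),
               rep("Holocentrinae", 4))
  expect_error(genusToSubfamily("Lutjanus"), class = "holocall_unknown_genus")
})

test_that("individual summaries average defined values and count sounds", {
  one <- data.frame(sound_id = "s", specimen_id = "sp", duration_ms = 74,
                    n_pulses = 6, period_ms = 9.5, lastpulse_ms = 17,
                    f0_hz = 115, fpeak_hz = 260, interval_ms = NA_real_,
                    n_blocks = 1, pulses_per_block = 6, p_class = "P3",
                    f0_quality_flag = FALSE, stringsAsFactors = FALSE)
  twenty <- one[rep(1, 20), ]
  twenty$sound_id <- paste0("s", 1:20)
  s <- summarizeIndividual(twenty)
  expect_equal(s$duration_ms, 74)
  expect_equal(s$f0_hz, 115)
  expect_equal(s$n_sounds, 20)
  expect_equal(s$pct_pattern, 0)
  expect_true(is.na(s$interval_ms))

  # interval defined for 5 of 20 sounds: mean over those 5 only
  mixed <- twenty
  mixed$interval_ms[1:5] <- c(16, 18, 20, 22, 24)
  mixed$n_blocks[1:5] <- 2
  sm <- summarizeIndividual(mixed)
  expect_equal(sm$interval_ms, 20)
  expect_equal(sm$pct_pattern, 25)

  # permutation invariance
  shuffled <- mixed[sample(20), ]
  expect_equal(summarizeIndividual(shuffled), sm)

  # uncooperative specimen with fewer sounds
  s12 <- summarizeIndividual(twenty[1:12, ])
  expect_equal(s12$n_sounds, 12)

  expect_error(summarizeIndividual(twenty[0, ]),
               class = "holocall_empty_input")
})

test_that("X(TL)^-1 normalization divides only the size-linked variables", {
  tab <- data.frame(specimen_id = c("a", "b", "c"),
                    duration_ms = c(74, 60, 50),
                    f0_hz = c(115, 100, 90),
                    n_pulses = c(6, 5, 4),
                    lastpulse_ms = c(17, 15, 13),
                    fpeak_hz = c(260, 280, 300),
                    TL_mm = c(200, 150, NA))
  expect_message(norm <- normalizeByLength(tab), "1 row")
  expect_equal(nrow(norm), 2)
  expect_equal(attr(norm, "n_dropped"), 1)
  expect_equal(norm$duration_ms[1], 0.37)          # 74 / 200
  expect_equal(norm$f0_hz, c(115, 100))            # not size-linked
  expect_equal(norm$fpeak_hz[2], 280 / 150)

  # un-normalization restores the originals to machine precision
  expect_equal(norm$duration_ms * norm$TL_mm, tab$duration_ms[1:2])

  bad <- tab; bad$TL_mm[1] <- -5
  expect_error(normalizeByLength(bad), class = "holocall_bad_tl")

  # TL is constant per individual: per-sound then average equals
  # average then normalize
  perSound <- tab[rep(1, 4), ]
  perSound$duration_ms <- c(70, 72, 76, 78)
  a <- mean(normalizeByLength(perSound)$duration_ms)
  b <- mean(perSound$duration_ms) / perSound$TL_mm[1]
  expect_equal(a, b)
})

test_that("size regressions recover a planted slope and behave under the null", {
  tpl <- taxonTemplate("slope", durationMs = c(60, 10), f0Hz = c(100, 15),
                       tlMm = c(180, 35), tlSlopes = list(duration_ms = 0.3))
  sim <- synthFeatureCohort(list(tpl), nIndividuals = 40, nSounds = 15, seed = 4)
  summ <- summarizeIndividuals(sim$features, sim$specimens)
  fits <- fitSizeRegressions(summ, variables = "duration_ms")
  est <- fits$slope[1]
  # standard error from the fit: the planted 0.3 must fall inside the 95% CI
  d <- summ[!is.na(summ$TL_mm), ]
  se <- summary(stats::lm(duration_ms ~ TL_mm, d))$coefficients[2, 2]
  expect_lt(abs(est - 0.3), 1.96 * se)

  # null slope: p-values uniform over replicates (KS at alpha 0.01)
  set.seed(99)
  pv <- replicate(200, {
    df <- data.frame(species = "x", TL_mm = rnorm(20, 180, 30),
                     duration_ms = rnorm(20, 60, 8))
    fitSizeRegressions(df, variables = "duration_ms")$p_value
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)

  # two-point species is skipped with a warning
  tiny <- data.frame(species = "y", TL_mm = c(100, 150),
                     duration_ms = c(50, 60))
  expect_warning(expect_error(fitSizeRegressions(tiny, "duration_ms"),
                              class = "holocall_empty_input"),
                 "skipped")
})

test_that("specimen metadata is validated on read", {
  td <- withr::local_tempdir()
  p <- file.path(td, "spec.csv")
  ok <- data.frame(specimen_id = "a1", species = "Myripristis berndti",
                   genus = "Myripristis", subfamily = "Myripristinae",
                   group = 2, TL_mm = 190, SL_mm = NA, site = "reef")
  write.csv(ok, p, row.names = FALSE, na = "")
  expect_equal(nrow(readSpecimens(p)), 1)

  bad <- ok; bad$subfamily <- "Holocentrinae"
  write.csv(bad, p, row.names = FALSE, na = "")
  expect_error(readSpecimens(p), class = "holocall_bad_metadata")

  expect_error(readSpecimens(file.path(td, "missing.csv")),
               class = "holocall_missing_file")
})
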