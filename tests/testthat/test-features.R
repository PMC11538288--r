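test_that("power spectrum localizes tones and honors the resolution contract", {
  t <- seq(0, 1, by = 1 / 44100)
  sp <- powerSpectrum(waveform(sin(2 * pi * 100 * t)))
  expect_lte(resolutionHz(sp), 5)
  expect_lt(abs(dominantFrequency(sp) - 100), 5)

  two <- waveform(sin(2 * pi * 100 * t) + 2 * sin(2 * pi * 300 * t))
  expect_lt(abs(dominantFrequency(powerSpectrum(two)) - 300), 5)

  # a 50 ms call has 20 Hz natural resolution; padding must reach ~5 Hz
  short <- waveform(sin(2 * pi * 300 * seq(0, 0.05, by = 1 / 44100)))
  sps <- powerSpectrum(short)
  expect_lte(resolutionHz(sps), 5)
  expect_lte(max(diff(freqsHz(sps))), 5)

  expect_error(powerSpectrum(short, targetResolutionHz = 0.01),
               class = "holocall_bad_resolution")
})

test_that("dominant frequency takes the maximal bin with low-frequency tie-break", {
  spec <- new("Spectrum", freqsHz = seq(0, 4000, by = 5),
              power = rep(0, 801), resolutionHz = 5)
  spec@power[freqsHz(spec) == 260] <- 1
  expect_equal(dominantFrequency(spec), 260)

  spec@power[freqsHz(spec) == 200] <- 2
  spec@power[freqsHz(spec) == 400] <- 2
  expect_equal(dominantFrequency(spec), 200)

  zero <- new("Spectrum", freqsHz = seq(0, 4000, by = 5),
              power = rep(0, 801), resolutionHz = 5)
  expect_error(dominantFrequency(zero), class = "holocall_zero_spectrum")
  expect_error(dominantFrequency(spec, bandHz = c(90000, 99000)),
               class = "holocall_bad_band")
})

test_that("fundamental frequency is the comb spacing, absent below 3 pulses", {
  call <- synthCall(fixedTemplate(f0 = 100, n = 7, snr = 30), seed = 2)
  w <- bandpassFilter(call$wave)
  tr <- detectPulses(w)
  spec <- powerSpectrum(w)
  f0 <- fundamentalFrequency(spec, tr)
  expect_lt(abs(as.numeric(f0) - 100), resolutionHz(spec) + 1e-9)

  # slow-period template: F0 ~ 1000/12.7 ~ 79 Hz within 10%
  slow <- fixedTemplate(f0 = 1000 / 12.7, n = 6, snr = 30)
  vals <- sapply(1:8, function(s) {
    cl <- synthCall(slow, seed = s)
    ww <- bandpassFilter(cl$wave)
    as.numeric(fundamentalFrequency(powerSpectrum(ww), detectPulses(ww)))
  })
  expect_lt(abs(mean(vals) - 1000 / 12.7) / (1000 / 12.7), 0.10)

  two <- synthCall(fixedTemplate(n = 2, snr = 30), seed = 3)
  w2 <- bandpassFilter(two$wave)
  expect_true(is.na(fundamentalFrequency(powerSpectrum(w2), detectPulses(w2))))
})

test_that("extractFeatures fills applicable variables and the P class", {
  # 7 pulses, one block
  call <- synthCall(fixedTemplate(f0 = 100, n = 7, res = 300, snr = 25), seed = 6)
  w <- bandpassFilter(call$wave)
  tr <- detectPulses(w)
  f <- extractFeatures(w, tr, segmentBlocks(periodsMs(tr)), "s1", "sp1")
  expect_equal(f$p_class, "P3")
  expect_equal(f$n_blocks, 1)
  expect_true(is.na(f$interval_ms))
  expect_equal(f$n_pulses, 7)
  expect_gt(f$duration_ms, 0)

  # 6 pulses in three blocks of two
  tpl <- fixedTemplate(f0 = 100, n = 6, res = 300, snr = 25, pattern = 1,
                       nBlocks = c(3, 0), interval = c(25, 0))
  call2 <- synthCall(tpl, seed = 8)
  expect_equal(call2$truth$nBlocks, 3)
  w2 <- bandpassFilter(call2$wave)
  tr2 <- detectPulses(w2)
  f2 <- extractFeatures(w2, tr2, segmentBlocks(periodsMs(tr2)), "s2", "sp1")
  expect_equal(f2$p_class, "P4")
  expect_equal(f2$n_blocks, 3)
  expect_equal(f2$pulses_per_block, 2)
  expect_false(is.na(f2$interval_ms))

  # single pulse: period, F0, interval all absent
  call3 <- synthCall(fixedTemplate(n = 1, snr = 25), seed = 9)
  w3 <- bandpassFilter(call3$wave)
  tr3 <- detectPulses(w3)
  f3 <- extractFeatures(w3, tr3, segmentBlocks(periodsMs(tr3)), "s3", "sp1")
  expect_equal(f3$p_class, "P1")
  expect_true(is.na(f3$period_ms))
  expect_true(is.na(f3$f0_hz))
  expect_true(is.na(f3$interval_ms))

  # mismatched block structure is rejected
  expect_error(extractFeatures(w, tr, segmentBlocks(c(10, 10))),
               class = "holocall_inconsistent_blocks")
})

test_that("extraction is deterministic and round-trips through CSV", {
  call <- synthCall(fixedTemplate(f0 = 90, n = 5, snr = 25), seed = 11)
  w <- bandpassFilter(call$wave)
  tr <- detectPulses(w)
  bl <- segmentBlocks(periodsMs(tr))
  f1 <- extractFeatures(w, tr, bl, "a", "b")
  f2 <- extractFeatures(w, tr, bl, "a", "b")
  expect_identical(f1, f2)

  td <- withr::local_tempdir()
  p <- file.path(td, "features.csv")
  tab <- rbind(f1, f2)
  tab$sound_id <- c("a1", "a2")
  writeFeatureTable(tab, p)
  back <- readFeatureTable(p)
  for (v in c("duration_ms", "period_ms", "f0_hz", "fpeak_hz", "lastpulse_ms"))
    expect_equal(back[[v]], tab[[v]], tolerance = 1e-6)
  expect_true(is.na(back$interval_ms[1]))
})

test_that("period and F0 are reciprocal within 20% on synthetic calls", {
  tpl <- holocentridTemplates()$Myripristinae
  for (s in 1:15) {
    call <- synthCall(tpl, seed = 400 + s)
    w <- bandpassFilter(call$wave)
    tr <- detectPulses(w)
    if (nPulses(tr) < 3) next
    f <- suppressWarnings(
      extractFeatures(w, tr, segmentBlocks(periodsMs(tr)), "x", "y"))
    if (is.na(f$f0_hz) || f$n_blocks > 1) next  # intervals inflate the mean period
    expect_gt(f$period_ms * f$f0_hz, 800)
    expect_lt(f$period_ms * f$f0_hz, 1200)
  }
})
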