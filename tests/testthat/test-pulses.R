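test_that("pulse detection recovers a clean 7-pulse train within 1 ms", {
  tpl <- fixedTemplate(f0 = 100, n = 7, res = 300, snr = 20)
  for (s in 1:5) {
    call <- synthCall(tpl, seed = s)
    tr <- detectPulses(bandpassFilter(call$wave))
    expect_equal(nPulses(tr), 7)
    expect_lt(max(abs(peakTimesMs(tr) - call$truth$pulseTimesMs)), 1)
    expect_equal(length(periodsMs(tr)), 6)
    expect_true(all(periodsMs(tr) > 0))
  }
})

test_that("sub-threshold input yields an empty train; a single pulse yields one", {
  set.seed(42)
  noise <- waveform(rnorm(44100, 0, 0.01))
  tr <- detectPulses(noise)
  expect_equal(nPulses(tr), 0)
  expect_length(periodsMs(tr), 0)

  call <- synthCall(fixedTemplate(n = 1, snr = 30), seed = 2)
  tr1 <- detectPulses(bandpassFilter(call$wave))
  expect_equal(nPulses(tr1), 1)
  expect_length(periodsMs(tr1), 0)
})

test_that("SNR estimate tracks the generator and is scale invariant", {
  tpl <- fixedTemplate(snr = 20)
  ests <- sapply(1:8, function(s) {
    call <- synthCall(tpl, seed = s)
    tr <- detectPulses(bandpassFilter(call$wave))
    estimateSnr(call$wave, tr)
  })
  expect_true(all(abs(ests - 20) < 3))

  call <- synthCall(tpl, seed = 3)
  tr <- detectPulses(bandpassFilter(call$wave))
  s1 <- estimateSnr(call$wave, tr)
  scaled <- waveform(samples(call$wave) * 0.35, rateHz(call$wave))
  expect_equal(estimateSnr(scaled, tr), s1, tolerance = 1e-8)

  # doubled noise floor must lower the estimate
  set.seed(9)
  noisier <- waveform(samples(call$wave) + rnorm(length(samples(call$wave)), 0, 0.05))
  expect_lt(estimateSnr(noisier, tr), s1)

  # noiseless call: the floor is set by pulse-tail leakage past the guard,
  # far above any operating SNR
  clean <- synthCall(fixedTemplate(snr = Inf), seed = 5)
  trc <- detectPulses(bandpassFilter(clean$wave))
  expect_gte(estimateSnr(clean$wave, trc, guardMs = 15), 40)

  empty <- new("PulseTrain", peakTimesMs = numeric(0),
               peakAmplitudes = numeric(0), soundOnsetMs = 0, soundOffsetMs = 0)
  expect_error(estimateSnr(call$wave, empty), class = "holocall_empty_train")
})

test_that("best-sound selection keeps top-k by SNR with index tie-break", {
  set.seed(7)
  snr <- sample(seq(5, 35, by = 0.5), 60)
  sel <- selectBestSounds(snr, k = 20)
  expect_length(sel, 20)
  expect_true(all(diff(sel) > 0))               # original order preserved
  expect_setequal(sel, order(snr, decreasing = TRUE)[1:20])

  expect_length(selectBestSounds(rnorm(12), k = 20), 12)
  # two equal values at the cut: lower index wins
  expect_equal(selectBestSounds(c(10, 20, 10, 5), k = 2), c(1, 2))
  expect_error(selectBestSounds(numeric(0)), class = "holocall_empty_input")
})

test_that("last-pulse duration follows the exponential closed form and scales", {
  tpl4 <- fixedTemplate(f0 = 80, n = 5, res = 350, tau = 4, snr = 35)
  d4 <- sapply(1:12, function(s) {
    call <- synthCall(tpl4, seed = s)
    w <- bandpassFilter(call$wave)
    measureLastPulseDuration(w, detectPulses(w))
  })
  expect_lt(abs(mean(d4) / (4 * log(10)) - 1), 0.15)

  tpl8 <- fixedTemplate(f0 = 80, n = 5, res = 350, tau = 8, snr = 35)
  d8 <- sapply(1:12, function(s) {
    call <- synthCall(tpl8, seed = s)
    w <- bandpassFilter(call$wave)
    measureLastPulseDuration(w, detectPulses(w))
  })
  expect_lt(abs(mean(d8) / mean(d4) - 2), 0.3)

  # pattern-rich template: measured last pulse lands within 2 sd of target
  tpl <- holocentridTemplates()$Myripristis_group2
  dm <- sapply(1:25, function(s) {
    call <- synthCall(tpl, seed = 100 + s)
    w <- bandpassFilter(call$wave)
    measureLastPulseDuration(w, detectPulses(w))
  })
  expect_lt(abs(mean(dm) - 17.3), 2 * sd(dm))

  w <- bandpassFilter(synthCall(tpl4, seed = 1)$wave)
  empty <- new("PulseTrain", peakTimesMs = numeric(0),
               peakAmplitudes = numeric(0), soundOnsetMs = 0, soundOffsetMs = 0)
  expect_error(measureLastPulseDuration(w, empty),
               class = "holocall_empty_train")
})

test_that("clean-cohort recovery: pulse counts exact and periods within 5%", {
  tpls <- holocentridTemplates()[c("Myripristinae", "Holocentrinae")]
  nExact <- 0; tot <- 0; perOk <- TRUE
  for (tpl in tpls) {
    for (s in 1:40) {
      call <- synthCall(tpl, seed = 5000 + s)
      tr <- detectPulses(bandpassFilter(call$wave))
      tot <- tot + 1
      if (nPulses(tr) == call$truth$nPulses) {
        nExact <- nExact + 1
        if (call$truth$nPulses > 1) {
          rel <- abs(mean(periodsMs(tr)) - mean(call$truth$periodsMs)) /
            mean(call$truth$periodsMs)
          perOk <- perOk && rel < 0.05
        }
      }
    }
  }
  expect_gte(nExact / tot, 0.99)
  expect_true(perOk)
})
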