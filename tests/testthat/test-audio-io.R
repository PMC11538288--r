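test_that("WAV round trip preserves silence and amplitudes within quantization", {
  td <- withr::local_tempdir()
  p <- file.path(td, "silence.wav")
  writeWav(waveform(numeric(44100)), p)
  w <- readWav(p)
  expect_equal(length(samples(w)), 44100)
  expect_true(all(samples(w) == 0))
  expect_equal(rateHz(w), 44100)

  call <- synthCall(fixedTemplate(), seed = 4)
  p2 <- file.path(td, "call.wav")
  writeWav(call$wave, p2)
  back <- readWav(p2)
  expect_equal(length(samples(back)), length(samples(call$wave)))
  expect_lte(max(abs(samples(back) - samples(call$wave))), 2^-15)
})

test_that("stereo input with identical channels reads as either channel", {
  td <- withr::local_tempdir()
  x <- 0.5 * sin(2 * pi * 440 * seq(0, 0.05, by = 1 / 44100))
  p <- file.path(td, "stereo.wav")
  writeStereoWav(x, x, p)
  w <- readWav(p)
  expect_equal(length(samples(w)), length(x))
  expect_lte(max(abs(samples(w) - x)), 2^-15)
})

test_that("reader raises distinct named errors", {
  td <- withr::local_tempdir()
  expect_error(readWav(file.path(td, "nope.wav")),
               class = "holocall_missing_file")
  bad <- file.path(td, "not_audio.wav")
  writeLines("this is not audio", bad)
  expect_error(readWav(bad), class = "holocall_not_audio")
  # valid header, zero-length data chunk
  z <- file.path(td, "empty.wav")
  con <- file(z, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")
  writeBin(c(44100L, 88200L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(readWav(z), class = "holocall_zero_length")
})

test_that("band-pass keeps the band, rejects out-of-band, preserves timing", {
  t <- seq(0, 1, by = 1 / 44100)
  inband <- waveform(sin(2 * pi * 1000 * t))
  y <- bandpassFilter(inband)
  expect_equal(length(samples(y)), length(samples(inband)))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(samples(y)) / rms(samples(inband)) - 1), 0.05)

  low <- waveform(sin(2 * pi * 10 * t))
  expect_lte(rms(samples(bandpassFilter(low))) / rms(samples(low)), 0.01)

  # impulse train at 100 Hz spacing: peak times shift by less than 1 sample
  x <- numeric(44100)
  idx <- seq(4410, 39690, by = 441)
  x[idx] <- 1
  yf <- samples(bandpassFilter(waveform(x)))
  for (i in idx[seq(1, length(idx), by = 8)]) {
    win <- (i - 200):(i + 200)
    expect_lte(abs(win[which.max(abs(yf[win]))] - i), 1)
  }
})

test_that("conditioning is idempotent in-band and validates edges", {
  t <- seq(0, 0.5, by = 1 / 44100)
  w <- waveform(0.4 * sin(2 * pi * 300 * t) + 0.3 * sin(2 * pi * 900 * t))
  once <- bandpassFilter(w)
  twice <- bandpassFilter(once)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(samples(twice)) / rms(samples(once)) - 1), 0.01)

  expect_error(bandpassFilter(w, loHz = 0), class = "holocall_bad_band")
  expect_error(bandpassFilter(w, loHz = 500, hiHz = 100),
               class = "holocall_bad_band")
  expect_error(bandpassFilter(w, hiHz = 44100), class = "holocall_bad_band")
})

test_that("non-canonical rates and widths are normalized on read", {
  td <- withr::local_tempdir()
  # write a 22050 Hz file through the package writer, then read it back
  x <- sin(2 * pi * 500 * seq(0, 0.1, by = 1 / 22050))
  p <- file.path(td, "lowrate.wav")
  writeWav(waveform(x, rateHz = 22050), p)
  w <- readWav(p)
  expect_equal(rateHz(w), 44100)
  expect_equal(length(samples(w)), floor((length(x) - 1) / 22050 * 44100) + 1)
})
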