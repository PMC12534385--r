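test_that("harmonic levels follow the -5 dB/harmonic roll-off below 1 kHz", {
  lv <- harmonic_levels(harmonic_complex(200, 2, 3))
  expect_equal(lv$order, 2:4)
  expect_equal(lv$freq_hz, c(400, 600, 800))
  expect_equal(lv$level_db, c(0, -5, -10))   # attenuation 0 below 1 kHz
})

test_that("log-linear attenuation hits its anchor points", {
  expect_equal(pitchsync:::spectral_attenuation_db(1000), 0)
  expect_equal(pitchsync:::spectral_attenuation_db(3000), -3)
  expect_equal(pitchsync:::spectral_attenuation_db(15900), -20)
  # held constant beyond the last anchor
  expect_equal(pitchsync:::spectral_attenuation_db(20000), -20)
  # log-linear midpoint of the first segment
  expect_equal(pitchsync:::spectral_attenuation_db(sqrt(3e6)), -1.5)
})

test_that("harmonics at or above Nyquist raise a named error", {
  spec <- harmonic_complex(4000, 5, 3)       # top harmonic 28 kHz
  expect_error(harmonic_levels(spec, sample_rate_hz = 44100), "order")
})

test_that("synthesis produces the expected spectrum and envelope", {
  spec <- harmonic_complex(200, 2, 1)
  x <- synthesize_complex(spec, 44100)
  expect_equal(length(x), round(0.6 * 44100))
  # fades reach zero at the ends
  expect_lt(abs(x[1]), 1e-6)
  expect_lt(abs(x[length(x)]), 1e-6)
  # FFT peak at 400 Hz for the single-component case
  sp <- Mod(stats::fft(as.numeric(x)))[1:(length(x) / 2)]
  f <- (seq_along(sp) - 1) * 44100 / length(x)
  expect_lt(abs(f[which.max(sp)] - 400), 2)

  # second partial of a 3-harmonic complex sits ~5 dB below the first
  x3 <- synthesize_complex(harmonic_complex(200, 2, 3), 44100)
  sp3 <- Mod(stats::fft(as.numeric(x3)))
  bin <- function(freq) round(freq * length(x3) / 44100) + 1
  rel_db <- 20 * log10(sp3[bin(600)] / sp3[bin(400)])
  expect_lt(abs(rel_db - (-5)), 0.5)
})

test_that("waveform RMS matches the analytic component RMS", {
  spec <- harmonic_complex(220, 2, 4)
  sr <- 44100
  x <- synthesize_complex(spec, sr)
  lv <- harmonic_levels(spec, sr)
  amps <- 10^(lv$level_db / 20)
  scale <- max(abs(x)) / max(abs({
    t <- (seq_len(length(x)) - 1) / sr
    rowSums(sapply(seq_along(amps), function(k)
      amps[k] * sin(2 * pi * lv$freq_hz[k] * t)))
  }))
  # compare over the unfaded central section
  nf <- round(spec$fade_s * sr)
  core <- x[(nf + 1):(length(x) - nf)]
  rms_analytic <- sqrt(sum(amps^2) / 2) * scale
  expect_lt(abs(sqrt(mean(core^2)) - rms_analytic) / rms_analytic, 0.01)
})

test_that("WAV writer emits a valid RIFF header and round-trips samples", {
  x <- synthesize_complex(harmonic_complex(200, 2, 2), 8000)
  path <- tempfile(fileext = ".wav")
  write_wav(x, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_equal(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, size = 4))
  expect_equal(readChar(con, 8), "WAVEfmt ")
  invisible(readBin(con, integer(), 1, size = 4))   # fmt chunk size
  invisible(readBin(con, integer(), 2, size = 2))   # format tag, channels
  sr <- readBin(con, integer(), 1, size = 4)
  expect_equal(sr, 8000)
})
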