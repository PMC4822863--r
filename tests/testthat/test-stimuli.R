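# Stimulus synthesis: ladder arithmetic, tone/vowel structure, telephone
# filtering, level calibration, WAV round trips.

test_that("semitone ladder covers the pitch range with 1/12-octave steps", {
  lad <- semitone_ladder(98, 493)
  expect_length(lad, 29)
  expect_equal(lad[1], 98)
  # printed upper endpoint is the truncated 29th note
  expect_equal(lad[29], 98 * 2^(28 / 12), tolerance = 1e-12)
  expect_equal(diff(log2(lad)), rep(1 / 12, 28), tolerance = 1e-9)
  expect_true(all(diff(lad) > 0))

  expect_equal(semitone_ladder(440, 440), 440)
  octave <- semitone_ladder(98, 196)
  expect_length(octave, 13)
  expect_identical(octave[13], 196)
  expect_error(semitone_ladder(-10, 100), "positive")
  expect_error(semitone_ladder(0, 100), "positive")
})

test_that("pure tones are zero-phase sinusoids of the right length", {
  w <- pure_tone(110, 0.5, 16000)
  expect_s3_class(w, "waveform")
  expect_length(w$samples, 8000)
  expect_equal(w$samples[1], 0)               # zero phase at t = 0
  # spectral peak at 110 Hz: 55 full periods in 0.5 s -> bin 56
  spec <- Mod(stats::fft(w$samples))[1:4000]
  expect_equal(which.max(spec), 55 + 1)
  # exactly 55 periods: the signal continues periodically across the end
  raw <- pure_tone(110, 0.5, 16000, level_db_spl = NA)
  expect_equal(raw$samples[1:100],
               sin(2 * pi * 110 * (8000:8099) / 16000), tolerance = 1e-9)

  expect_length(pure_tone(110, 0, 16000)$samples, 0)
  expect_error(pure_tone(8000, 0.5, 16000), "Nyquist")
  expect_error(pure_tone(-5, 0.5, 16000), "positive")
})

test_that("cascade vowels are periodic with formant-region spectral peaks", {
  v <- klatt_vowel(standard_vowel("a", 110))
  expect_length(v$samples, 8000)
  # period ~9.09 ms: autocorrelation peak at lag 1/f0 within one sample
  ac <- stats::acf(v$samples, lag.max = 200, plot = FALSE)$acf[-1]
  lag <- which.max(ac[100:200]) + 99
  expect_lt(abs(lag - 16000 / 110), 1)
  # strongest spectral component near each of the first two formants
  # (within half a harmonic spacing, since energy sits on f0 harmonics)
  spec <- Mod(stats::fft(v$samples))^2
  f <- (seq_along(spec) - 1) * 16000 / length(spec)
  peak_in <- function(lo, hi) {
    w <- which(f >= lo & f <= hi)
    f[w[which.max(spec[w])]]
  }
  expect_lt(abs(peak_in(500, 950) - 710), 60)
  expect_lt(abs(peak_in(950, 1400) - 1150), 60)

  # zero formants: the raw impulse train, one pulse per period
  imp <- klatt_vowel(vowel_spec(110, matrix(numeric(0), ncol = 2)),
                     level_db_spl = NA)
  expect_equal(sum(imp$samples != 0), 55)
  expect_true(all(imp$samples %in% c(0, 1)))

  expect_error(klatt_vowel(standard_vowel("a", 110), rate = 4000),
               "Nyquist")
  expect_error(vowel_spec(110, rbind(c(800, 50), c(700, 50))), "increasing")
  expect_error(vowel_spec(110, rbind(c(700, 0))), "positive")
})

test_that("telephone filter meets its band specification and is linear", {
  # steady-state RMS (the abrupt on/offset of a finite snippet splatters
  # broadband energy through any high-pass filter; the band behaviour is
  # defined away from the edges)
  mid <- 2000:6000
  rms <- function(x) sqrt(mean(x[mid]^2))
  tone110 <- pure_tone(110)
  tone1k <- pure_tone(1000)
  att110 <- 20 * log10(rms(telephone_filter(tone110)$samples) /
                         rms(tone110$samples))
  att1k <- 20 * log10(rms(telephone_filter(tone1k)$samples) /
                        rms(tone1k$samples))
  expect_lt(att110, -80)
  expect_lt(abs(att1k), 1)

  z <- waveform(numeric(800))
  expect_equal(telephone_filter(z)$samples, numeric(800))

  a <- pure_tone(150); b <- pure_tone(900)
  mix <- waveform(2 * a$samples - 0.5 * b$samples)
  lhs <- telephone_filter(mix)$samples
  rhs <- 2 * telephone_filter(a)$samples - 0.5 * telephone_filter(b)$samples
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_error(telephone_filter(waveform(rnorm(100), rate = 8000)),
               "16 kHz")
})

test_that("level calibration follows the 94 dB full-scale convention", {
  w <- set_level(pure_tone(220, level_db_spl = NA), 60)
  expect_equal(sqrt(mean(w$samples^2)), 10^((60 - 94) / 20) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(sound_level(w), 60, tolerance = 1e-9)
  w80 <- set_level(w, 80)
  expect_equal(sqrt(mean(w80$samples^2)) / sqrt(mean(w$samples^2)), 10,
               tolerance = 1e-9)
  expect_error(set_level(waveform(numeric(100)), 60), "silence")
})

test_that("WAV files round-trip, fold to mono and resample", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  w <- pure_tone(220)
  write_wav(w, tmp, bits = 16)
  r <- read_wav(tmp)
  expect_equal(r$rate, 16000)
  expect_lte(max(abs(r$samples - w$samples)), 1 / 32768)
  write_wav(w, tmp, bits = 32)
  expect_lte(max(abs(read_wav(tmp)$samples - w$samples)), 1e-6)

  # interleaved stereo PCM16 file written by hand: first channel kept
  st <- withr::local_tempfile(fileext = ".wav")
  ch1 <- round(sin(2 * pi * 440 * (0:999) / 16000) * 16000)
  ch2 <- rep(0L, 1000)
  con <- file(st, "wb")
  wr <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  writeChar("RIFF", con, eos = NULL); wr(36 + 4000, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr(16, 4)
  wr(1, 2); wr(2, 2); wr(16000, 4); wr(64000, 4); wr(4, 2); wr(16, 2)
  writeChar("data", con, eos = NULL); wr(4000, 4)
  wr(as.vector(rbind(ch1, ch2)), 2)
  close(con)
  rs <- read_wav(st)
  expect_length(rs$samples, 1000)
  expect_equal(rs$samples, ch1 / 32768, tolerance = 1e-9)

  # 44.1 kHz -> 16 kHz: duration preserved within one sample
  hi <- waveform(sin(2 * pi * 440 * (0:44099) / 44100), rate = 44100)
  write_wav(hi, tmp, bits = 32)
  lo <- read_wav(tmp, rate = 16000)
  expect_lte(abs(length(lo$samples) - 16000), 1)

  expect_error(read_wav(file.path(tempdir(), "missing-file.wav")),
               "missing-file")
})
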