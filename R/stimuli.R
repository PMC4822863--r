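# Stimulus synthesis: pure-tone semitone ladder, cascade-formant vowels,
# high-pass "telephone" variants, level calibration and WAV file handling.
# All standard stimuli are 0.5 s, 16 kHz, 60 dB SPL.

#' Construct a waveform object
#'
#' A `waveform` is the model's only external-facing input: a sampled sound
#' pressure signal with its sampling rate, nominal presentation level and a
#' free-text label.
#'
#' @param samples Numeric vector of pressure samples (calibrated arbitrary
#'   units; see [set_level()] for the dB SPL convention).
#' @param rate Sampling rate in samples/s.
#' @param level_db_spl Nominal presentation level in dB SPL (`NA` if
#'   uncalibrated).
#' @param label Free-text label.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate = 16000, level_db_spl = NA_real_,
                     label = "") {
  samples <- as.numeric(samples)
  if (length(samples) && any(!is.finite(samples)))
    stop("waveform samples must be finite")
  if (rate <= 0) stop("sampling rate must be positive")
  structure(list(samples = samples, rate = rate,
                 level_db_spl = level_db_spl, label = label),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform '%s': %d samples @ %g Hz (%.3g s), %s dB SPL>\n",
              x$label, length(x$samples), x$rate,
              length(x$samples) / x$rate,
              format(x$level_db_spl)))
  invisible(x)
}

# RMS level convention: a full-scale sinusoid (peak amplitude 1) corresponds
# to 94 dB SPL, so rms_ref = 10^(-94/20)/sqrt(2) maps RMS to dB SPL.
.full_scale_spl <- 94

#' Equal-tempered semitone ladder
#'
#' Frequencies `f_low * 2^(k/12)` for `k = 0..K` with
#' `K = round(12 * log2(f_high / f_low))`, so the nominal `[98, 493]` Hz
#' pitch range yields the 29 notes G2--B4 (the printed upper endpoint 493 Hz
#' is B4 truncated; the ladder ends at 493.88 Hz).
#'
#' @param f_low,f_high Range endpoints in Hz.
#' @return Ascending numeric vector of frequencies (Hz).
#' @examples
#' length(semitone_ladder(98, 493)) # 29
#' @export
semitone_ladder <- function(f_low, f_high) {
  if (f_low <= 0 || f_high <= 0) stop("frequencies must be positive")
  if (f_high < f_low) stop("f_high must be >= f_low")
  k <- round(12 * log2(f_high / f_low))
  f_low * 2^((0:k) / 12)
}

#' Synthesize a pure tone
#'
#' `sin(2 * pi * freq * t)`, zero phase at `t = 0`, RMS-calibrated to
#' `level_db_spl`.
#'
#' @param freq Frequency in Hz; must lie below the Nyquist rate.
#' @param duration Duration in seconds.
#' @param rate Sampling rate in samples/s.
#' @param level_db_spl Presentation level (dB SPL); `NA` leaves the unit
#'   amplitude unscaled.
#' @return A [waveform].
#' @export
pure_tone <- function(freq, duration = 0.5, rate = 16000,
                      level_db_spl = 60) {
  if (freq <= 0) stop("frequency must be positive")
  if (freq >= rate / 2) stop("frequency must be below the Nyquist rate")
  n <- round(duration * rate)
  s <- if (n > 0) sin(2 * pi * freq * (0:(n - 1)) / rate) else numeric(0)
  w <- waveform(s, rate, NA_real_, sprintf("tone %.5g Hz", freq))
  if (!is.na(level_db_spl) && n > 0) w <- set_level(w, level_db_spl)
  w
}

#' Vowel specification
#'
#' Fundamental frequency plus formant resonances (center frequency and
#' bandwidth, both Hz) for cascade synthesis.
#'
#' @param f0 Fundamental frequency (Hz).
#' @param formants Two-column matrix or list of `c(center, bandwidth)` pairs,
#'   centers strictly increasing, bandwidths positive.
#' @return An object of class `vowel_spec`.
#' @export
vowel_spec <- function(f0, formants) {
  if (f0 <= 0) stop("f0 must be positive")
  if (is.list(formants)) formants <- do.call(rbind, formants)
  formants <- matrix(as.numeric(formants), ncol = 2,
                     dimnames = list(NULL, c("center", "bandwidth")))
  if (nrow(formants) > 1 && any(diff(formants[, 1]) <= 0))
    stop("formant centers must be strictly increasing")
  if (any(formants[, 2] <= 0)) stop("formant bandwidths must be positive")
  structure(list(f0 = f0, formants = formants), class = "vowel_spec")
}

#' Built-in vowel formant tables
#'
#' Cascade-formant parameters for the sustained vowels used throughout:
#' /a/ with formants 710/1150/2700 Hz (bandwidths 40/43/105 Hz) and /i/ with
#' 230/2000/3000 Hz (bandwidths 68/63/129 Hz).
#'
#' @param vowel `"a"` or `"i"`.
#' @param f0 Fundamental frequency (Hz).
#' @return A [vowel_spec].
#' @export
standard_vowel <- function(vowel = c("a", "i"), f0 = 110) {
  vowel <- match.arg(vowel)
  fmts <- switch(vowel,
                 a = rbind(c(710, 40), c(1150, 43), c(2700, 105)),
                 i = rbind(c(230, 68), c(2000, 63), c(3000, 129)))
  vowel_spec(f0, fmts)
}

# Digital resonator (cascade-synthesizer second-order section):
# y[n] = A x[n] + B y[n-1] + C y[n-2] with unity gain at DC.
.resonator <- function(x, center, bandwidth, rate) {
  C <- -exp(-2 * pi * bandwidth / rate)
  B <- 2 * exp(-pi * bandwidth / rate) * cos(2 * pi * center / rate)
  A <- 1 - B - C
  as.numeric(signal::filter(signal::Arma(b = A, a = c(1, -B, -C)), x))
}

#' Synthesize a sustained vowel (cascade branch)
#'
#' An impulse train at `f0` is passed through cascaded second-order
#' resonators, one per formant, giving a periodic waveform with period
#' `1/f0` and spectral peaks at the formant centers. Only the cascade
#' branch is modelled (no glottal source shaping, no parallel branch).
#'
#' @param spec A [vowel_spec].
#' @inheritParams pure_tone
#' @return A [waveform].
#' @export
klatt_vowel <- function(spec, duration = 0.5, rate = 16000,
                        level_db_spl = 60) {
  stopifnot(inherits(spec, "vowel_spec"))
  if (any(spec$formants[, 1] >= rate / 2))
    stop("formant centers must be below the Nyquist rate")
  n <- round(duration * rate)
  x <- numeric(n)
  if (n > 0) {
    idx <- unique(floor(seq(0, duration - 1e-12, by = 1 / spec$f0) * rate)) + 1
    x[idx[idx <= n]] <- 1
  }
  for (k in seq_len(nrow(spec$formants)))
    x <- .resonator(x, spec$formants[k, 1], spec$formants[k, 2], rate)
  w <- waveform(x, rate, NA_real_,
                sprintf("vowel f0=%.5g Hz", spec$f0))
  if (!is.na(level_db_spl) && n > 0) w <- set_level(w, level_db_spl)
  w
}

# Kaiser-window high-pass FIR used for the telephone-line simulation.
# The band specification (stop <= 300 Hz at >= 80 dB, pass >= 350 Hz within
# 1 dB, fs = 16 kHz) needs ~1800 taps; designed once and cached.
.telephone_cache <- new.env(parent = emptyenv())
.telephone_fir <- function() {
  if (is.null(.telephone_cache$h)) {
    n <- 1800
    beta <- 0.1102 * (80 - 8.7)
    .telephone_cache$h <- signal::fir1(n, 325 / 8000, type = "high",
                                       window = signal::kaiser(n + 1, beta))
  }
  .telephone_cache$h
}

#' High-pass "telephone" filter
#'
#' Removes spectral content below 300 Hz (including the fundamental of most
#' ladder pitches), simulating a telephone transmission line: stop-band
#' attenuation of at least 80 dB at and below 300 Hz and pass-band ripple
#' within 1 dB at and above 350 Hz. The linear-phase FIR group delay is
#' compensated (filter-then-trim), so filtered and unfiltered stimuli stay
#' aligned channel-by-channel downstream.
#'
#' @param w A [waveform] sampled at 16 kHz.
#' @return The filtered [waveform] (same length).
#' @export
telephone_filter <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate != 16000) stop("telephone_filter expects a 16 kHz waveform")
  h <- .telephone_fir()
  n <- length(w$samples)
  if (n == 0) return(w)
  delay <- (length(h) - 1) / 2
  y <- stats::convolve(c(w$samples, numeric(delay)), rev(h), type = "open")
  w$samples <- y[(delay + 1):(delay + n)]
  w$label <- paste0(w$label, " [telephone]")
  w
}

#' Measure or set the presentation level
#'
#' Level convention: a full-scale sinusoid (peak amplitude 1, RMS
#' `1/sqrt(2)`) is defined as 94 dB SPL, so
#' `SPL = 94 + 20*log10(rms * sqrt(2))`. The downstream spike-rate
#' calibration absorbs the absolute scale; the convention only fixes
#' relative levels.
#'
#' @param w A [waveform] with nonzero RMS.
#' @param target_db_spl Desired level in dB SPL.
#' @return `set_level`: the rescaled [waveform]; `sound_level`: dB SPL.
#' @export
set_level <- function(w, target_db_spl) {
  stopifnot(inherits(w, "waveform"))
  r <- sqrt(mean(w$samples^2))
  if (!length(w$samples) || r == 0) stop("cannot set the level of silence")
  target_rms <- 10^((target_db_spl - .full_scale_spl) / 20) / sqrt(2)
  w$samples <- w$samples * (target_rms / r)
  w$level_db_spl <- target_db_spl
  w
}

#' @rdname set_level
#' @export
sound_level <- function(w) {
  stopifnot(inherits(w, "waveform"))
  r <- sqrt(mean(w$samples^2))
  if (!length(w$samples) || r == 0) return(-Inf)
  .full_scale_spl + 20 * log10(r * sqrt(2))
}

#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE support: 16-bit PCM and 32-bit IEEE float, read and
#' write. Multi-channel files are reduced to the first channel; files at
#' other sampling rates are resampled to `rate` (duration preserved within
#' one sample).
#'
#' @param path File path.
#' @param rate Target sampling rate for reading (Hz).
#' @param w A [waveform] to write.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `read_wav`: a [waveform]; `write_wav`: `path`, invisibly.
#' @export
read_wav <- function(path, rate = 16000) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels     = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      if (fmt$audio_format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", sz / 4, 4, endian = "little")
      } else stop("unsupported WAV encoding in ", path)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk in WAV file: ", path)
  if (fmt$channels > 1)
    samples <- samples[seq(1, length(samples), by = fmt$channels)]
  if (fmt$sample_rate != rate) {
    g <- .gcd(rate, fmt$sample_rate)
    samples <- as.numeric(
      signal::resample(samples, rate / g, fmt$sample_rate / g))
  }
  waveform(samples, rate, NA_real_, basename(path))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' @rdname read_wav
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 32))
  x <- w$samples
  bytes <- bits / 8
  data_sz <- length(x) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  wr_int <- function(v, size) writeBin(as.integer(v), con, size = size,
                                       endian = "little")
  writeChar("RIFF", con, eos = NULL); wr_int(36 + data_sz, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr_int(16, 4)
  wr_int(if (bits == 16) 1 else 3, 2)          # PCM / IEEE float
  wr_int(1, 2)                                 # mono
  wr_int(w$rate, 4)
  wr_int(w$rate * bytes, 4)                    # byte rate
  wr_int(bytes, 2); wr_int(bits, 2)
  writeChar("data", con, eos = NULL); wr_int(data_sz, 4)
  if (bits == 16) {
    wr_int(pmax(-32768, pmin(32767, round(x * 32768))), 2)
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Build the standard stimulus set
#'
#' All synthetic stimulus classes on one pitch ladder: pure tones, /a/ and
#' /i/ vowels, and their high-pass telephone variants (0.5 s, 16 kHz,
#' 60 dB SPL each).
#'
#' @param pitches Pitch ladder in Hz (default the 29-note `[98, 493]` Hz
#'   semitone ladder).
#' @param types Character subset of
#'   `c("tone", "vowel_a", "vowel_i", "telephone_a", "telephone_i")`.
#' @param duration,rate,level_db_spl Shared stimulus parameters.
#' @return A list with `waves` (list of [waveform]s) and `manifest`
#'   (data.frame with `label`, `type`, `pitch_hz`).
#' @export
stimulus_set <- function(pitches = semitone_ladder(98, 493),
                         types = c("tone", "vowel_a", "vowel_i",
                                   "telephone_a", "telephone_i"),
                         duration = 0.5, rate = 16000, level_db_spl = 60) {
  types <- match.arg(types, several.ok = TRUE)
  waves <- list(); manifest <- NULL
  for (ty in types) for (f0 in pitches) {
    w <- switch(ty,
      tone        = pure_tone(f0, duration, rate, level_db_spl),
      vowel_a     = klatt_vowel(standard_vowel("a", f0), duration, rate,
                                level_db_spl),
      vowel_i     = klatt_vowel(standard_vowel("i", f0), duration, rate,
                                level_db_spl),
      telephone_a = telephone_filter(klatt_vowel(standard_vowel("a", f0),
                                                 duration, rate,
                                                 level_db_spl)),
      telephone_i = telephone_filter(klatt_vowel(standard_vowel("i", f0),
                                                 duration, rate,
                                                 level_db_spl)))
    key <- sprintf("%s_%.5g", ty, f0)
    waves[[key]] <- w
    manifest <- rbind(manifest,
                      data.frame(label = key, type = ty, pitch_hz = f0))
  }
  list(waves = waves, manifest = manifest)
}
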