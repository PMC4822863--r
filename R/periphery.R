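# Phase I: simplified auditory periphery. Middle-ear band-pass, gammatone
# filterbank at Greenwood characteristic frequencies, inner-hair-cell
# transduction (half-wave rectification + 1 kHz low-pass), and the
# time-averaged place code of pitch.

#' Greenwood frequency-position map
#'
#' `CF(d) = 165.4 * (10^(2.1 * d / 34) - 1)` gives the characteristic
#' frequency (Hz) of the cochlear position `d` (mm from the apex);
#' `greenwood_position` is the closed-form inverse.
#'
#' @param d_mm Cochlear position(s) in mm from the apex (nonnegative).
#' @param cf_hz Characteristic frequency/frequencies in Hz (nonnegative).
#' @return Frequency in Hz / position in mm.
#' @examples
#' round(greenwood_cf(3)) # 88
#' @export
greenwood_cf <- function(d_mm) {
  if (any(d_mm < 0)) stop("cochlear position must be nonnegative")
  165.4 * (10^(2.1 * d_mm / 34) - 1)
}

#' @rdname greenwood_cf
#' @export
greenwood_position <- function(cf_hz) {
  if (any(cf_hz < 0)) stop("characteristic frequency must be nonnegative")
  34 / 2.1 * log10(cf_hz / 165.4 + 1)
}

#' Tonotopic cochlear map
#'
#' Cochlear positions 3--22.9 mm in 0.1 mm steps (200 channels by default)
#' with characteristic frequencies from the Greenwood map, spanning ~88 Hz
#' to ~4.1 kHz. A smaller `n_channels` spreads the same positional range
#' more coarsely (used by the miniature fixtures).
#'
#' @param n_channels Number of channels.
#' @param d_range Positional range in mm from the apex.
#' @return An object of class `cochlear_map` with `positions_mm` and
#'   `cfs_hz`.
#' @export
cochlear_map <- function(n_channels = 200, d_range = c(3, 22.9)) {
  stopifnot(n_channels >= 1)
  pos <- seq(d_range[1], d_range[2], length.out = n_channels)
  structure(list(positions_mm = pos, cfs_hz = greenwood_cf(pos)),
            class = "cochlear_map")
}

#' @export
print.cochlear_map <- function(x, ...) {
  cat(sprintf("<cochlear_map: %d channels, %.4g-%.4g mm, CF %.3g-%.5g Hz>\n",
              length(x$cfs_hz), min(x$positions_mm), max(x$positions_mm),
              min(x$cfs_hz), max(x$cfs_hz)))
  invisible(x)
}

# Causal 4th-order gammatone impulse response at one CF, unit gain at CF.
# ERB-scaled bandwidth; L samples long.
.gammatone_ir <- function(cf, rate, L) {
  t <- (0:(L - 1)) / rate
  erb <- 24.7 * (4.37 * cf / 1000 + 1)
  b <- 1.019 * erb
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  gain <- abs(sum(g * exp(-2i * pi * cf * t)))
  g / gain
}

#' Spatio-temporal activity map (Phase I)
#'
#' Runs the waveform through a first-order middle-ear band-pass
#' (0.1--6 kHz), a bank of 4th-order gammatone filters centered at the
#' map's characteristic frequencies, then an inner-hair-cell stage
#' (half-wave rectification followed by a 2nd-order 1 kHz Butterworth
#' low-pass). The result is a nonnegative channels-by-time matrix whose
#' rows are ordered tonotopically; its entries are instantaneous IHC
#' activity in arbitrary units (the spike-rate calibration downstream
#' fixes the absolute scale).
#'
#' @param w A [waveform] at 16 kHz.
#' @param map A [cochlear_map].
#' @param ir_ms Gammatone impulse-response length (ms) used in the FFT
#'   convolution.
#' @return An object of class `stmap` with `activity` (channels x time),
#'   `rate` and `map`.
#' @export
auditory_periphery <- function(w, map = cochlear_map(), ir_ms = 64) {
  stopifnot(inherits(w, "waveform"), inherits(map, "cochlear_map"))
  n <- length(w$samples)
  if (n == 0) stop("cannot process an empty waveform")
  fs <- w$rate
  # middle ear: first-order Butterworth band-pass 0.1-6 kHz
  me <- signal::butter(1, c(100, 6000) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(me, w$samples))
  # gammatone bank via FFT convolution with causal IRs
  L <- round(ir_ms / 1000 * fs)
  nfft <- stats::nextn(n + L - 1, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  nch <- length(map$cfs_hz)
  act <- matrix(0, nch, n)
  lp <- signal::butter(2, 1000 / (fs / 2), type = "low")
  for (j in seq_len(nch)) {
    ir <- .gammatone_ir(map$cfs_hz[j], fs, L)
    y <- Re(stats::fft(X * stats::fft(c(ir, numeric(nfft - L))),
                       inverse = TRUE)) / nfft
    y <- pmax(y[seq_len(n)], 0)                       # IHC rectification
    act[j, ] <- pmax(as.numeric(signal::filter(lp, y)), 0)
  }
  structure(list(activity = act, rate = fs, map = map), class = "stmap")
}

#' @export
print.stmap <- function(x, ...) {
  cat(sprintf("<stmap: %d channels x %d samples @ %g Hz>\n",
              nrow(x$activity), ncol(x$activity), x$rate))
  invisible(x)
}

#' Place code of pitch
#'
#' Per-channel temporal mean of the spatio-temporal map over a 100 ms
#' window (after skipping the onset transient), normalized to maximum 1.
#' Pure tones give a single peak at the channel whose CF matches the tone;
#' vowels give formant-region peaks.
#'
#' @param stm An `stmap` from [auditory_periphery()].
#' @param window_ms Averaging window length (ms).
#' @param skip_ms Onset interval excluded from averaging (ms); shortened
#'   automatically if the signal is too short for `skip + window`.
#' @return Numeric vector of normalized per-channel rates in `[0, 1]`
#'   (all-zero input gives an all-zero code).
#' @export
place_code <- function(stm, window_ms = 100, skip_ms = 50) {
  stopifnot(inherits(stm, "stmap"))
  n <- ncol(stm$activity)
  win <- round(window_ms / 1000 * stm$rate)
  if (win > n) stop("averaging window longer than the signal")
  skip <- min(round(skip_ms / 1000 * stm$rate), n - win)
  r <- rowMeans(stm$activity[, (skip + 1):(skip + win), drop = FALSE])
  m <- max(r)
  if (m > 0) r <- r / m
  r
}
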