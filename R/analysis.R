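# Temporal pitch-code extraction: vector-strength matrices quantify phase
# locking of each pitch neuron to each stimulus; pooled inter-spike-
# interval histograms (1 ms bins over 0-50 ms, span-3 smoothed, max-
# normalized) carry the temporal code, read out as the dominant interval.

#' Vector strength (phase locking)
#'
#' Resultant length of spike phases at a reference frequency:
#' `|sum_k exp(2i * pi * freq * t_k)| / N`, 1 for perfect locking, ~1/sqrt(N)
#' for random spike times, and defined as 0 for an empty train. Phase is
#' referenced to stimulus onset (t = 0).
#'
#' @param times Spike times (s), referenced to stimulus onset.
#' @param freq Reference frequency (Hz), positive.
#' @return Scalar in `[0, 1]`.
#' @export
vector_strength <- function(times, freq) {
  if (freq <= 0) stop("reference frequency must be positive")
  n <- length(times)
  if (n == 0) return(0)
  Mod(sum(exp(2i * pi * freq * times))) / n
}

#' Vector-strength matrix
#'
#' Entry (i, k) is the vector strength of pitch neuron i's response to
#' stimulus k, evaluated at stimulus k's pitch frequency. Each stimulus is
#' presented `analysis_reps` times (default 10 x 0.5 s = a 5 s interval)
#' with fresh Poisson draws; spike phases are referenced to the onset of
#' their own presentation, since the stimulus restarts each time. A
#' trained model shows a dominant diagonal (strongest locking to the
#' matched pitch); the untrained model shows none.
#'
#' @param model A [pitch_snn] fit.
#' @param stim_type Stimulus type presented (default pure tones).
#' @param weights Optional weight-matrix override (e.g.
#'   `model$weights_initial`).
#' @param seed Integer seed.
#' @return A pitches x pitches matrix of vector strengths in `[0, 1]`.
#' @export
vs_matrix <- function(model, stim_type = "tone", weights = NULL, seed = 1) {
  stopifnot(inherits(model, "pitch_snn"))
  np <- length(model$pitches)
  out <- matrix(0, np, np,
                dimnames = list(neuron = sprintf("%.5g", model$pitches),
                                stimulus = sprintf("%.5g", model$pitches)))
  seeds <- .sub_seeds(seed, np)
  for (k in seq_len(np)) {
    wav <- .category_wave(stim_type, model$pitches[k])
    reps <- simulate(model, nsim = model$control$analysis_reps,
                     seed = seeds[k], waveform = wav, weights = weights)
    for (i in seq_len(np)) {
      times <- unlist(lapply(reps, `[[`, i), use.names = FALSE)
      out[i, k] <- vector_strength(times, model$pitches[k])
    }
  }
  out
}

# span-3 moving average; endpoint windows shrink to the sample itself
# (padding the edges would double-count the neighbour and can promote an
# empty first bin above a full second one)
.smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

#' Pooled inter-spike-interval histogram
#'
#' Intervals (consecutive by default, or all-order) are computed within
#' each train, pooled across trains, and binned in 1 ms bins over
#' `[0, max_ms]`. The histogram is also span-3 smoothed (endpoint windows
#' shrink) and normalized to maximum.
#'
#' @param trains List of sorted spike-time vectors (s); intervals are
#'   never taken across trains, so gaps between repeated presentations
#'   contribute nothing.
#' @param bin_ms Bin width (ms).
#' @param max_ms Longest interval retained (ms).
#' @param order `"first"` (consecutive intervals) or `"all"` (all ordered
#'   pairs up to `max_ms`, as in all-order interval analyses).
#' @param pitch_label Optional pitch label (Hz) carried in the object.
#' @return An object of class `isih`: `counts` (integer), `smoothed`
#'   (max 1 unless empty), `mids` (bin centers, ms), `n_intervals`,
#'   `pitch_label`.
#' @export
pooled_isih <- function(trains, bin_ms = 1, max_ms = 50,
                        order = c("first", "all"), pitch_label = NA_real_) {
  order <- match.arg(order)
  if (inherits(trains, "lif_sim")) trains <- trains$trains
  if (is.numeric(trains)) trains <- list(trains)
  isi <- unlist(lapply(trains, function(t) {
    if (length(t) < 2) return(numeric(0))
    if (order == "first") diff(t)
    else {
      d <- outer(t, t, "-")
      d[d > 0 & d <= max_ms / 1000]
    }
  }), use.names = FALSE) * 1000
  isi <- isi[isi > 0 & isi <= max_ms]
  breaks <- seq(0, max_ms, by = bin_ms)
  counts <- as.integer(table(cut(isi, breaks, right = TRUE)))
  sm <- .smooth3(as.numeric(counts))
  if (max(sm) > 0) sm <- sm / max(sm)
  structure(list(counts = counts, smoothed = sm,
                 mids = breaks[-1] - bin_ms / 2,
                 n_intervals = length(isi), pitch_label = pitch_label),
            class = "isih")
}

#' @export
print.isih <- function(x, ...) {
  cat(sprintf("<isih: %d intervals in %d bins of %g ms%s>\n",
              x$n_intervals, length(x$counts), diff(x$mids[1:2]),
              if (is.na(x$pitch_label)) ""
              else sprintf(", pitch %.5g Hz", x$pitch_label)))
  invisible(x)
}

#' Dominant interval of a histogram
#'
#' Center of the maximal smoothed bin, the temporal code of pitch; ties
#' are broken towards the shorter interval.
#'
#' @param h An [pooled_isih()] object.
#' @return Interval in ms.
#' @export
dominant_interval <- function(h) {
  stopifnot(inherits(h, "isih"))
  if (h$n_intervals == 0) stop("empty histogram: no intervals to rank")
  h$mids[which.max(h$smoothed)]
}

#' Histogram peaks and their spacing
#'
#' Local maxima of the smoothed histogram at or above `min_height`
#' (relative to the maximum); plateaus count once, at their shorter-
#' interval edge. `isih_peak_spacing` returns the median spacing between
#' adjacent peaks, the inter-peak readout of the stimulus period.
#'
#' @param h An [pooled_isih()] object.
#' @param min_height Minimum relative peak height.
#' @return `isih_peaks`: peak centers (ms); `isih_peak_spacing`: median
#'   adjacent-peak spacing (ms, `NA` with fewer than two peaks).
#' @export
isih_peaks <- function(h, min_height = 0.25) {
  stopifnot(inherits(h, "isih"))
  s <- h$smoothed
  n <- length(s)
  if (n < 3) return(h$mids[which.max(s)])
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  idx <- which(s > left & s >= right & s >= min_height)
  h$mids[idx]
}

#' @rdname isih_peaks
#' @export
isih_peak_spacing <- function(h, min_height = 0.25) {
  p <- isih_peaks(h, min_height)
  if (length(p) < 2) return(NA_real_)
  stats::median(diff(p))
}

#' Stacked pooled ISIHs across the pitch ladder
#'
#' Presents one stimulus per pitch category to the trained model and
#' stacks the resulting pooled ISIHs by ascending pitch. Rows of a trained
#' model show the dominant interval tracking the stimulus period (shorter
#' intervals, and fewer/stronger peaks, at higher pitch).
#'
#' @param model A [pitch_snn] fit.
#' @param stim_type Stimulus type presented.
#' @param weights Optional weight-matrix override.
#' @param seed Integer seed.
#' @param reps Presentations pooled per category (defaults to the model's
#'   `analysis_reps`).
#' @return An object of class `stacked_isih`: a list of [pooled_isih()]
#'   objects ordered by ascending pitch, with attribute `pitches`.
#' @export
stacked_isih <- function(model, stim_type = "tone", weights = NULL,
                         seed = 1, reps = NULL) {
  stopifnot(inherits(model, "pitch_snn"))
  reps <- reps %||% model$control$analysis_reps
  np <- length(model$pitches)
  seeds <- .sub_seeds(seed, np)
  rows <- vector("list", np)
  for (k in seq_len(np)) {
    wav <- .category_wave(stim_type, model$pitches[k])
    sims <- simulate(model, nsim = reps, seed = seeds[k], waveform = wav,
                     weights = weights)
    rows[[k]] <- pooled_isih(unlist(sims, recursive = FALSE),
                             pitch_label = model$pitches[k])
  }
  structure(rows, pitches = model$pitches, class = "stacked_isih")
}

#' @export
print.stacked_isih <- function(x, ...) {
  cat(sprintf("<stacked_isih: %d pitch categories, %.4g-%.5g Hz>\n",
              length(x), min(attr(x, "pitches")), max(attr(x, "pitches"))))
  invisible(x)
}
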