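# Auditory-nerve spike generation: IHC activity is read as the
# time-dependent intensity of an inhomogeneous Poisson process, one per
# channel. Refractoriness lives in the output-neuron model, not here, so
# the trains are pure Poisson.

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Deterministically expand a master seed into per-use 31-bit sub-seeds.
.sub_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Calibrate IHC activity to spike rates
#'
#' Maps a spatio-temporal activity map to Poisson intensities through a
#' saturating (Michaelis-Menten) transduction,
#' `lambda = peak_rate * a / (a + a50)` with the half-saturation point
#' `a50 = sat_frac * max(a)`, rescaled so the maximum instantaneous
#' intensity across channels equals `peak_rate` (spikes/s). Saturation is
#' the auditory nerve's normal operating regime at conversational levels:
#' it bounds the rate any single channel can carry, so the drive a
#' stimulus delivers is necessarily distributed over many afferents
#' rather than concentrated in the channel at its spectral peak, while
#' the within-period modulation (the phase information downstream
#' plasticity feeds on) is preserved by the half-wave-rectified envelope
#' passing through zero. `sat_frac = Inf` gives the linear limit. The
#' default `peak_rate` in [snn_control()] was fixed by a one-off
#' calibration sweep so that an untrained output neuron (uniform initial
#' weights) fires at the high initial rate (~80 spike/s) that accelerates
#' early plasticity.
#'
#' @param stm An `stmap` from [auditory_periphery()].
#' @param peak_rate Target maximum instantaneous rate (spikes/s).
#' @param sat_frac Half-saturation activity as a fraction of the map's
#'   maximum.
#' @return An object of class `rate_envelope`: `lambda` (channels x time,
#'   spikes/s), `rate` (samples/s), `duration_s`.
#' @export
calibrate_rates <- function(stm, peak_rate, sat_frac = 0.1) {
  stopifnot(inherits(stm, "stmap"), peak_rate > 0, sat_frac > 0)
  m <- max(stm$activity)
  if (m == 0) stop("cannot calibrate an all-zero activity map")
  lam <- if (is.finite(sat_frac)) {
    a50 <- sat_frac * m
    sat <- stm$activity / (stm$activity + a50)
    sat * (peak_rate / max(sat))
  } else {
    stm$activity * (peak_rate / m)
  }
  structure(list(lambda = lam, rate = stm$rate,
                 duration_s = ncol(stm$activity) / stm$rate,
                 cfs_hz = stm$map$cfs_hz,
                 lambda_max = apply(lam, 1, max)),
            class = "rate_envelope")
}

#' Inhomogeneous Poisson spike trains
#'
#' Draws one spike train per channel by thinning against the channel's
#' maximum intensity; the intensity is piecewise constant at the audio
#' sample resolution, so thinning is exact for the sampled envelope.
#' Expected spike count per channel equals the integral of its intensity.
#'
#' @param env A `rate_envelope` from [calibrate_rates()], or a single
#'   numeric intensity vector (one channel).
#' @param seed Integer seed (reproducible trains); `NULL` uses the current
#'   RNG stream.
#' @param rate Samples/s of `env` when it is a plain vector.
#' @return A list of sorted numeric spike-time vectors (seconds), one per
#'   channel, with attribute `duration_s`.
#' @export
poisson_spikes <- function(env, seed = NULL, rate = 16000) {
  if (is.numeric(env))
    env <- structure(list(lambda = matrix(env, nrow = 1), rate = rate,
                          duration_s = length(env) / rate),
                     class = "rate_envelope")
  stopifnot(inherits(env, "rate_envelope"))
  lam <- env$lambda
  dur <- env$duration_s
  fs <- env$rate
  nch <- nrow(lam)
  nt <- ncol(lam)
  lmax <- env$lambda_max %||% apply(lam, 1, max)
  .with_seed(seed, {
    n_j <- stats::rpois(nch, pmax(lmax, 0) * dur)
    tot <- sum(n_j)
    trains <- rep(list(numeric(0)), nch)
    if (tot > 0) {
      ch <- rep.int(seq_len(nch), n_j)
      t <- stats::runif(tot, 0, dur)
      bin <- pmin(floor(t * fs) + 1L, nt)
      keep <- stats::runif(tot) * lmax[ch] < lam[cbind(ch, bin)]
      trains <- lapply(unname(split(t[keep],
                                    factor(ch[keep],
                                           levels = seq_len(nch)))),
                       sort)
    }
    attr(trains, "duration_s") <- dur
    trains
  })
}

#' Spike-event file I/O
#'
#' Serializes a list of spike trains as a two-column tab-delimited event
#' table (`neuron_id`, `time_s`) preceded by `#`-prefixed JSON header lines
#' carrying the duration and number of neurons. This is the interchange
#' format between the spike-generation, network and analysis stages.
#'
#' @param trains List of numeric spike-time vectors.
#' @param path File path.
#' @return `write_spike_events`: `path` invisibly; `read_spike_events`: a
#'   list of spike-time vectors with attribute `duration_s`.
#' @export
write_spike_events <- function(trains, path) {
  dur <- attr(trains, "duration_s")
  hdr <- sprintf("# %s", jsonlite::toJSON(
    list(n_neurons = length(trains), duration_s = dur), auto_unbox = TRUE))
  df <- data.frame(
    neuron_id = rep(seq_along(trains), lengths(trains)),
    time_s = unlist(trains, use.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  if (!file.exists(path)) stop("cannot read spike events: ", path)
  hdr <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  trains <- lapply(seq_len(meta$n_neurons),
                   function(i) sort(df$time_s[df$neuron_id == i]))
  attr(trains, "duration_s") <- meta$duration_s
  trains
}
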