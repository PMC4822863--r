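# The user-facing fitted model: pitch_snn() trains the 29 x 200 plastic
# weight matrix (one output neuron per ladder pitch, each trained on its
# own category) and returns a classed object with the usual accessor and
# simulation methods.

#' Simulation and training control settings
#'
#' Numerical and scheduling knobs that are not part of the scientific
#' parameter set. `eta_scale`/`time_scale` implement desk-scale training:
#' the learning rate is multiplied by `eta_scale` and the learning time
#' divided by `time_scale` (defaults 100/100 preserve the `eta * T`
#' product, so the endpoint matches full-scale training in the
#' slow-learning regime while needing 1% of the simulated time).
#' `peak_rate` and `sat_frac` parameterize the saturating
#' activity-to-intensity transduction of [calibrate_rates()]; the
#' defaults were fixed once by a calibration sweep so that an untrained
#' neuron (uniform `w0`) fires in the high initial regime (~80 spike/s
#' on a mid-ladder pure tone).
#'
#' @param eta_scale Learning-rate multiplier (> 0).
#' @param time_scale Learning-time divisor (> 0).
#' @param dt LIF integration step (s), at most 1e-4.
#' @param peak_rate Poisson calibration constant (spikes/s): the
#'   saturated per-channel intensity ceiling.
#' @param sat_frac Half-saturation activity of the transduction as a
#'   fraction of each map's maximum (see [calibrate_rates()]).
#' @param analysis_reps Number of fresh 0.5 s presentations concatenated
#'   for analysis-stage measures (10 gives the standard 5 s interval).
#' @param record_trace Keep per-presentation learning traces?
#' @return A list of class `snn_control`.
#' @export
snn_control <- function(eta_scale = 100, time_scale = 100, dt = 1e-4,
                        peak_rate = 2000, sat_frac = 0.01,
                        analysis_reps = 10, record_trace = TRUE) {
  stopifnot(eta_scale > 0, time_scale > 0, dt > 0, peak_rate > 0,
            sat_frac > 0, analysis_reps >= 1)
  structure(list(eta_scale = eta_scale, time_scale = time_scale, dt = dt,
                 peak_rate = peak_rate, sat_frac = sat_frac,
                 analysis_reps = analysis_reps,
                 record_trace = record_trace),
            class = "snn_control")
}

# Envelope cache: periphery + rate calibration for a list of waveforms.
.make_envelopes <- function(waves, map, control) {
  lapply(waves, function(w)
    calibrate_rates(auditory_periphery(w, map), control$peak_rate,
                    control$sat_frac))
}

#' Fit the spiking pitch model
#'
#' Trains one conductance-based LIF "pitch neuron" per ladder pitch with
#' the asymmetric STDP rule: during training, each neuron is presented
#' only with stimuli of its own pitch category (repeated 0.5 s
#' presentations with fresh Poisson draws), its 200 afferent weights
#' starting uniform at `w0`. In `"mixed"` mode the stimulus type of each
#' category is drawn at random from the tone and vowel classes, emulating
#' a varied listening environment; single-type modes use one class
#' throughout.
#'
#' @param pitches Pitch ladder (Hz); default the 29-note semitone ladder
#'   over `[98, 493]` Hz.
#' @param type One of `"tone"`, `"vowel_a"`, `"vowel_i"`, `"telephone_a"`,
#'   `"telephone_i"`, `"mixed"`.
#' @param params An [snn_params].
#' @param map A [cochlear_map].
#' @param control An [snn_control].
#' @param seed Integer master seed; all Poisson draws and the mixed-type
#'   assignment derive from it.
#' @param runs Number of independent mixed-type runs (each with a fresh
#'   random type assignment) whose weight matrices are averaged
#'   element-wise; ignored for single-type training. Averaging washes out
#'   run-specific spectral stripes — and the handful of weights a single
#'   run rails against the bounds — while the pitch-related structure
#'   common to all runs survives; the pooled temporal readouts are
#'   computed from the averaged matrix.
#' @param .stim_cache Internal: shared per-category envelope cache used
#'   by repeated runs.
#' @return An object of class `pitch_snn` with components `weights`
#'   (pitches x channels, dimnames = pitch Hz / CF Hz), `weights_initial`,
#'   `weights_snapshot` (10% of learning), `pitches`, `type`,
#'   `type_assignment`, `map`, `params`, `control`, `trace` (list of
#'   per-neuron learning traces), `seed`.
#' @seealso [vs_matrix()], [stacked_isih()], [pitch_ranking_experiment()]
#' @export
pitch_snn <- function(pitches = semitone_ladder(98, 493),
                      type = c("tone", "vowel_a", "vowel_i",
                               "telephone_a", "telephone_i", "mixed"),
                      params = snn_params(), map = cochlear_map(),
                      control = snn_control(), seed = 1, runs = 1,
                      .stim_cache = NULL) {
  type <- match.arg(type)
  if (runs > 1 && type == "mixed") {
    run_seeds <- .sub_seeds(seed + 7L, runs)
    stim_cache <- new.env(parent = emptyenv())
    fits <- lapply(run_seeds, function(s)
      pitch_snn(pitches, type, params, map, control, seed = s, runs = 1,
                .stim_cache = stim_cache))
    shared <- new.env(parent = emptyenv())
    for (f in seq_along(fits)) fits[[f]]$env_cache <- shared
    ens <- fits[[1]]
    # element-wise mean across runs: the run-averaged connectivity
    # pattern (type-specific stripes wash out, the pitch wrinkle stays)
    ens$weights <- mixed_type_average(lapply(fits, coef))
    ens$weights_snapshot <-
      mixed_type_average(lapply(fits, `[[`, "weights_snapshot"))
    ens$runs <- runs
    ens$run_fits <- fits
    ens$type_assignment <- lapply(fits, `[[`, "type_assignment")
    ens$seed <- seed
    ens$env_cache <- shared
    return(ens)
  }
  n_pitch <- length(pitches)
  nch <- length(map$cfs_hz)
  base_types <- c("tone", "vowel_a", "vowel_i")
  assignment <- if (type == "mixed") {
    .with_seed(seed, sample(base_types, n_pitch, replace = TRUE))
  } else rep(type, n_pitch)
  seeds <- .sub_seeds(seed + 1L, n_pitch)
  W <- matrix(NA_real_, n_pitch, nch,
              dimnames = list(pitch_hz = sprintf("%.5g", pitches),
                              cf_hz = sprintf("%.5g", map$cfs_hz)))
  Wsnap <- W
  traces <- vector("list", n_pitch)
  for (i in seq_len(n_pitch)) {
    ck <- sprintf("%s_%.6g", assignment[i], pitches[i])
    env <- if (!is.null(.stim_cache) && !is.null(.stim_cache[[ck]])) {
      .stim_cache[[ck]]
    } else {
      e <- .make_envelopes(list(.category_wave(assignment[i], pitches[i])),
                           map, control)
      if (!is.null(.stim_cache)) .stim_cache[[ck]] <- e
      e
    }
    fit <- train_pitch_neuron(env, params, control, seed = seeds[i])
    W[i, ] <- fit$w
    Wsnap[i, ] <- fit$w_snapshot
    if (control$record_trace) traces[[i]] <- fit$trace
  }
  structure(list(weights = W,
                 weights_initial = matrix(params$w0, n_pitch, nch,
                                          dimnames = dimnames(W)),
                 weights_snapshot = Wsnap,
                 pitches = pitches, type = type,
                 type_assignment = assignment, map = map, params = params,
                 control = control, trace = traces, seed = seed,
                 env_cache = new.env(parent = emptyenv())),
            class = "pitch_snn")
}

# Envelope for a stimulus, memoized in the model's cache by label.
.model_envelope <- function(object, waveform) {
  key <- sprintf("%s#%d", waveform$label, length(waveform$samples))
  cache <- object$env_cache
  if (is.null(cache)) return(
    .make_envelopes(list(waveform), object$map, object$control)[[1]])
  if (is.null(cache[[key]]))
    cache[[key]] <- .make_envelopes(list(waveform), object$map,
                                    object$control)[[1]]
  cache[[key]]
}

# One standard waveform of a given stimulus type and pitch.
.category_wave <- function(type, pitch, duration = 0.5) {
  switch(type,
    tone        = pure_tone(pitch, duration),
    vowel_a     = klatt_vowel(standard_vowel("a", pitch), duration),
    vowel_i     = klatt_vowel(standard_vowel("i", pitch), duration),
    telephone_a = telephone_filter(klatt_vowel(standard_vowel("a", pitch),
                                               duration)),
    telephone_i = telephone_filter(klatt_vowel(standard_vowel("i", pitch),
                                               duration)),
    stop("unknown stimulus type: ", type))
}

#' @export
print.pitch_snn <- function(x, ...) {
  cat(sprintf("<pitch_snn: %d pitch neurons (%.4g-%.5g Hz), %d afferents, '%s' training>\n",
              length(x$pitches), min(x$pitches), max(x$pitches),
              ncol(x$weights), x$type))
  cat(sprintf("  desk scale eta x%g / T / %g; seed %d\n",
              x$control$eta_scale, x$control$time_scale, x$seed))
  invisible(x)
}

#' @export
summary.pitch_snn <- function(object, ...) {
  rate0 <- vapply(object$trace, function(tr)
    if (is.null(tr)) NA_real_ else tr$rate[1], numeric(1))
  rate1 <- vapply(object$trace, function(tr)
    if (is.null(tr)) NA_real_ else mean(utils::tail(tr$rate, 10)),
    numeric(1))
  out <- list(pitches = object$pitches, type = object$type,
              initial_rate = rate0, final_rate = rate1,
              weight_range = range(object$weights),
              clipped = sum(vapply(object$trace, function(tr)
                if (is.null(tr)) 0L else sum(tr$clipped), integer(1))))
  class(out) <- "summary.pitch_snn"
  out
}

#' @export
print.summary.pitch_snn <- function(x, ...) {
  cat(sprintf("pitch_snn fit ('%s' training, %d neurons)\n", x$type,
              length(x$pitches)))
  cat(sprintf("  output rate: initial %.3g +/- %.2g sp/s -> final %.3g +/- %.2g sp/s\n",
              mean(x$initial_rate, na.rm = TRUE),
              stats::sd(x$initial_rate, na.rm = TRUE),
              mean(x$final_rate, na.rm = TRUE),
              stats::sd(x$final_rate, na.rm = TRUE)))
  cat(sprintf("  weights in [%.4g, %.4g]; %d updates clipped\n",
              x$weight_range[1], x$weight_range[2], x$clipped))
  invisible(x)
}

#' @export
coef.pitch_snn <- function(object, ...) object$weights

#' Plot the trained weight matrix
#'
#' Heatmap of synaptic efficacies with afferent CF on the abscissa and
#' pitch category on the ordinate; the pitch-related "wrinkle" runs from
#' bottom-left towards the top-middle.
#'
#' @param x A `pitch_snn` fit.
#' @param which `"final"`, `"snapshot"` or `"initial"` weights.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pitch_snn <- function(x, which = c("final", "snapshot", "initial"),
                           ...) {
  which <- match.arg(which)
  W <- switch(which, final = x$weights, snapshot = x$weights_snapshot,
              initial = x$weights_initial)
  graphics::image(x = x$map$cfs_hz, y = seq_along(x$pitches), z = t(W),
                  log = "x", xlab = "afferent CF (Hz)",
                  ylab = "pitch neuron (index, ascending pitch)",
                  main = sprintf("synaptic weights (%s)", which), ...)
  invisible(x)
}

#' Simulate trained responses to a stimulus
#'
#' Presents a waveform `nsim` times with fresh Poisson draws and returns
#' the output spike trains of every pitch neuron for each presentation.
#' For a run-averaged mixed fit, presentations rotate round-robin over
#' the member runs: the spiking nonlinearity does not commute with
#' weight averaging (the element-wise mean of run matrices is a model
#' none of the runs resembles, and is typically sub-threshold), so the
#' averaged "emerged dynamics" are realized by pooling responses across
#' runs rather than by simulating the averaged matrix.
#'
#' @param object A `pitch_snn` fit.
#' @param nsim Number of independent 0.5 s presentations.
#' @param seed Integer seed.
#' @param waveform The stimulus [waveform] (required).
#' @param weights Optional weight matrix overriding the fitted weights
#'   (e.g. `object$weights_initial` for the untrained model); disables
#'   member rotation.
#' @param ... Unused.
#' @return A list of `nsim` lists of per-neuron spike-time vectors, with
#'   attribute `duration_s` (single-presentation duration).
#' @export
simulate.pitch_snn <- function(object, nsim = 1, seed = NULL,
                               waveform = NULL, weights = NULL, ...) {
  if (is.null(waveform)) stop("a stimulus waveform is required")
  members <- if (is.null(weights) && !is.null(object$run_fits))
    lapply(object$run_fits, coef) else list(weights %||% object$weights)
  env <- .model_envelope(object, waveform)
  seeds <- .sub_seeds(seed %||% 1L, nsim)
  reps <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    W <- members[[(r - 1L) %% length(members) + 1L]]
    trains <- poisson_spikes(env, seed = seeds[r])
    reps[[r]] <- simulate_lif(W, trains, object$params,
                              dt = object$control$dt,
                              duration = env$duration_s)$trains
  }
  attr(reps, "duration_s") <- env$duration_s
  reps
}

#' Decode the pitch of a stimulus from the temporal code
#'
#' Presents the stimulus, pools inter-spike intervals across all pitch
#' neurons and presentations, and reads the dominant interval of the
#' pooled histogram as the period of the perceived pitch.
#'
#' @param object A `pitch_snn` fit.
#' @param waveform The stimulus [waveform].
#' @param nsim Presentations pooled.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list with `pitch_hz` (1000 / dominant interval in ms),
#'   `interval_ms` and the pooled `isih`.
#' @export
predict.pitch_snn <- function(object, waveform, nsim = 10, seed = 1, ...) {
  reps <- simulate(object, nsim = nsim, seed = seed, waveform = waveform)
  h <- pooled_isih(unlist(reps, recursive = FALSE))
  d <- dominant_interval(h)
  list(pitch_hz = 1000 / d, interval_ms = d, isih = h)
}
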