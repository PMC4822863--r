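# Conductance-based leaky integrate-and-fire output layer. Each pitch
# neuron integrates delayed, EPSC-shaped drive from the 200 Poisson
# afferents; integration is exponential-Euler on the linear-in-V membrane
# equation with the double-exponential kernel tracked as two auxiliary
# exponential state variables (exact for impulse inputs on the step grid).

#' Model parameters (Phase II)
#'
#' Neuron, synapse and plasticity parameters with their standard defaults:
#' membrane time constant 10 ms, threshold -50 mV, resting and reset
#' potentials -65 mV, reversal potential 0 mV, refractory period 1 ms,
#' synaptic delay 10 ms, EPSC rise/decay 0.5/1 ms; STDP gains 15/10 with
#' time constants 1/5 ms (net-depressing window, integral -0.035 s),
#' homeostatic coefficient `b_j = nu_bar * integral(W) = -1.05`, learning
#' rate 1e-7, learning time 5000 s, target rate 30 spike/s, initial weight
#' 0.0075, weight bounds [-0.2, 0.2].
#'
#' @param tau_m,v_th,v_p,v_r,v_rev,t_ref,delay,tau_a,tau_b LIF and synapse
#'   parameters (seconds / mV).
#' @param a_p,tau_p,a_d,tau_d STDP window gains and time constants
#'   (seconds).
#' @param eta,t_learn,nu_bar,w0,w_min,w_max Learning rate, learning time
#'   (s), target post-synaptic rate (spike/s), initial weight and bounds.
#' @return A list of class `snn_params`.
#' @export
snn_params <- function(tau_m = 0.010, v_th = -50, v_p = -65, v_r = -65,
                       v_rev = 0, t_ref = 0.001, delay = 0.010,
                       tau_a = 0.0005, tau_b = 0.001,
                       a_p = 15, tau_p = 0.001, a_d = 10, tau_d = 0.005,
                       eta = 1e-7, t_learn = 5000, nu_bar = 30,
                       w0 = 0.0075, w_min = -0.2, w_max = 0.2) {
  if (!(v_r <= v_p && v_p < v_th && v_th < v_rev))
    stop("potentials must satisfy v_r <= v_p < v_th < v_rev")
  if (tau_a >= tau_b) stop("EPSC rise time must be below the decay time")
  if (any(c(tau_m, t_ref, tau_a, tau_b, tau_p, tau_d) <= 0))
    stop("time constants must be positive")
  if (a_p <= 0 || a_d <= 0) stop("window gains must be positive")
  wint <- a_p * tau_p - a_d * tau_d
  if (wint >= 0)
    stop("the learning window must be net-depressing (a_p*tau_p < a_d*tau_d)")
  structure(list(tau_m = tau_m, v_th = v_th, v_p = v_p, v_r = v_r,
                 v_rev = v_rev, t_ref = t_ref, delay = delay,
                 tau_a = tau_a, tau_b = tau_b,
                 a_p = a_p, tau_p = tau_p, a_d = a_d, tau_d = tau_d,
                 w_integral = wint, b_j = nu_bar * wint,
                 eta = eta, t_learn = t_learn, nu_bar = nu_bar,
                 w0 = w0, w_min = w_min, w_max = w_max),
            class = "snn_params")
}

#' @export
print.snn_params <- function(x, ...) {
  cat("<snn_params>\n")
  cat(sprintf("  LIF: tau_m=%g ms, V_th=%g mV, V_p=V_r=%g mV, V_rev=%g mV, t_ref=%g ms, delay=%g ms\n",
              x$tau_m * 1e3, x$v_th, x$v_p, x$v_rev, x$t_ref * 1e3,
              x$delay * 1e3))
  cat(sprintf("  EPSC: tau_A=%g ms, tau_B=%g ms\n", x$tau_a * 1e3,
              x$tau_b * 1e3))
  cat(sprintf("  STDP: Ap=%g, tau_p=%g ms, Ad=%g, tau_d=%g ms, int W=%g s, b_j=%g\n",
              x$a_p, x$tau_p * 1e3, x$a_d, x$tau_d * 1e3, x$w_integral,
              x$b_j))
  cat(sprintf("  learning: eta=%g, T=%g s, nu_bar=%g sp/s, w0=%g, bounds=[%g, %g]\n",
              x$eta, x$t_learn, x$nu_bar, x$w0, x$w_min, x$w_max))
  invisible(x)
}

#' Double-exponential EPSC kernel
#'
#' `(exp(-t/tau_B) - exp(-t/tau_A)) / (tau_B - tau_A)` for `t >= 0` and 0
#' otherwise; unit integral, peak at `log(tau_B/tau_A)/(1/tau_A - 1/tau_B)`
#' (0.693 ms for the default 0.5/1 ms time constants).
#'
#' @param t Time(s) in seconds (vectorized).
#' @param params An [snn_params].
#' @return Kernel value(s) (1/s).
#' @export
epsc_kernel <- function(t, params = snn_params()) {
  if (params$tau_a == params$tau_b)
    stop("degenerate EPSC kernel: tau_A == tau_B")
  out <- (exp(-t / params$tau_b) - exp(-t / params$tau_a)) /
    (params$tau_b - params$tau_a)
  out[t < 0] <- 0
  out
}

# Delayed arrival times per channel, truncated to the simulation window.
.arrival_times <- function(trains, delay, duration) {
  lapply(trains, function(t) { a <- t + delay; a[a < duration] })
}

# Recursive single-pole filtering of the rows of a matrix (impulse counts
# per time step) -> summed decaying-exponential traces.
.exp_trace <- function(D, a) {
  t(stats::filter(t(D), a, method = "recursive"))
}

#' Simulate the LIF output layer
#'
#' Integrates the conductance-based membrane equation
#' `dV/dt = (V_p - V + sum_j w_j g_j(t) (V_rev - V)) / tau_m`
#' with exponential Euler at step `dt`, where `g_j` is the EPSC-kernel
#' trace of afferent `j`'s delayed spikes. A spike is emitted when `V`
#' crosses threshold; `V` is then clamped at the reset potential for the
#' absolute refractory period while synaptic conductances keep evolving.
#' Negative weights (allowed by the lower bound) enter the equation
#' literally and hyperpolarize.
#'
#' @param weights Numeric matrix (neurons x channels) or vector (one
#'   neuron) of synaptic efficacies.
#' @param inputs List of afferent spike-time vectors (seconds), one per
#'   channel.
#' @param params An [snn_params].
#' @param dt Integration step (s), at most 1e-4.
#' @param duration Simulated time (s).
#' @param record_v Keep per-neuron voltage traces (mV)?
#' @param negative_weights `"literal"` (default): negative efficacies
#'   enter the conductance equation as written and hyperpolarize;
#'   `"clip"`: treated as zero, for the reading in which all inputs are
#'   strictly excitatory and the lower weight bound merely brakes
#'   depression.
#' @return A list of class `lif_sim`: `trains` (list of output spike-time
#'   vectors), `dt`, `duration_s`, and optionally `v` (neurons x steps).
#' @export
simulate_lif <- function(weights, inputs, params = snn_params(),
                         dt = 1e-4, duration = 0.5, record_v = FALSE,
                         negative_weights = c("literal", "clip")) {
  if (dt > 1e-4 + 1e-12) stop("dt must be at most 0.1 ms")
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  if (match.arg(negative_weights) == "clip") weights <- pmax(weights, 0)
  m <- nrow(weights)
  nch <- ncol(weights)
  if (length(inputs) != nch)
    stop("weights have ", nch, " columns but ", length(inputs),
         " input trains were given")
  N <- round(duration / dt)
  arr <- .arrival_times(inputs, params$delay, duration)
  ns <- lengths(arr)
  if (sum(ns) > 0) {
    ch <- rep.int(seq_len(nch), ns)
    bins <- pmin(floor(unlist(arr, use.names = FALSE) / dt) + 1L, N)
    M <- Matrix::sparseMatrix(i = ch, j = bins, x = 1, dims = c(nch, N))
    D <- as.matrix(weights %*% M)
  } else {
    D <- matrix(0, m, N)
  }
  aA <- exp(-dt / params$tau_a)
  aB <- exp(-dt / params$tau_b)
  # The EPSC kernel is unit-normalized on the millisecond timescale
  # (integral 1 ms = 1e-3 s): this is the scale on which the printed
  # weight values are meaningful. With a unit-second integral a single
  # afferent spike at w0 would depolarize the cell by ~50 mV and fire it,
  # leaving no summation regime at all.
  g <- 1e-3 * (.exp_trace(D, aB) - .exp_trace(D, aA)) /
    (params$tau_b - params$tau_a)
  if (m == 1) g <- matrix(g, nrow = 1)
  v_p <- params$v_p; v_r <- params$v_r; v_th <- params$v_th
  # steady state and per-step decay are functions of g only: vectorize
  vinf_m <- (v_p + g * params$v_rev) / (1 + g)
  decay_m <- exp(-dt * (1 + g) / params$tau_m)
  if (any(!is.finite(vinf_m)) || any(!is.finite(decay_m)))
    stop("non-finite conductance state in LIF integration")
  n_ref_s <- max(1L, round(params$t_ref / dt))
  if (m == 1 && !record_v) {
    # scalar fast path (training runs dominate on this branch)
    vinf <- as.numeric(vinf_m)
    decay <- as.numeric(decay_m)
    v <- v_p
    refr <- 0L
    st <- numeric(512)
    ns <- 0L
    for (n in seq_len(N)) {
      if (refr > 0L) { refr <- refr - 1L; next }
      v <- vinf[n] + (v - vinf[n]) * decay[n]
      if (v >= v_th) {
        ns <- ns + 1L
        if (ns > length(st)) st <- c(st, numeric(length(st)))
        st[ns] <- n * dt
        v <- v_r
        refr <- n_ref_s
      }
    }
    trains <- list(st[seq_len(ns)])
    attr(trains, "duration_s") <- duration
    return(structure(list(trains = trains, dt = dt,
                          duration_s = duration), class = "lif_sim"))
  }
  v <- rep(v_p, m)
  refr <- integer(m)
  n_ref <- n_ref_s
  spikes <- vector("list", m)
  counts <- integer(m)
  for (i in seq_len(m)) spikes[[i]] <- numeric(256)
  vtrace <- if (record_v) matrix(NA_real_, m, N)
  for (n in seq_len(N)) {
    vinf <- vinf_m[, n]
    vnew <- vinf + (v - vinf) * decay_m[, n]
    active <- refr == 0L
    v[active] <- vnew[active]
    refr[!active] <- refr[!active] - 1L
    fired <- active & (v >= v_th)
    if (any(fired)) {
      tn <- n * dt
      for (i in which(fired)) {
        counts[i] <- counts[i] + 1L
        if (counts[i] > length(spikes[[i]]))
          spikes[[i]] <- c(spikes[[i]], numeric(length(spikes[[i]])))
        spikes[[i]][counts[i]] <- tn
      }
      v[fired] <- v_r
      refr[fired] <- n_ref
    }
    if (record_v) vtrace[, n] <- v
  }
  trains <- lapply(seq_len(m), function(i) spikes[[i]][seq_len(counts[i])])
  attr(trains, "duration_s") <- duration
  out <- list(trains = trains, dt = dt, duration_s = duration)
  if (record_v) out$v <- vtrace
  structure(out, class = "lif_sim")
}

#' Mean output firing rate
#'
#' Spike count inside a window divided by the window length, per neuron.
#'
#' @param sim A `lif_sim` (or a plain list of spike-time vectors).
#' @param window `c(start, end)` in seconds.
#' @return Numeric vector of rates (spikes/s).
#' @export
output_rate <- function(sim, window = NULL) {
  trains <- if (inherits(sim, "lif_sim")) sim$trains else sim
  if (is.null(window))
    window <- c(0, attr(trains, "duration_s") %||%
                  max(c(0, unlist(trains)), na.rm = TRUE))
  if (window[2] <= window[1]) stop("empty rate window")
  vapply(trains, function(t) sum(t > window[1] & t <= window[2]),
         numeric(1)) / (window[2] - window[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
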