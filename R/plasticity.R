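# Asymmetric STDP with a homeostatic rate term. The learning window is
# net-depressing (integral -0.035 s) so, together with
# b_j = nu_bar * integral(W), the post-synaptic rate is driven towards
# nu_bar while temporally-correlated synapses are strengthened.

#' STDP learning window
#'
#' `W(s) = A_p * exp(-s/tau_p)` for `s > 0` (pre-before-post,
#' potentiation) and `-A_d * exp(s/tau_d)` for `s < 0` (depression), with
#' `s` the post-synaptic minus the pre-synaptic spike time; `W(0) = 0`.
#' Depression extends further in time than potentiation
#' (`A_d*tau_d > A_p*tau_p`), giving the negative integral
#' `A_p*tau_p - A_d*tau_d = -0.035` s at the default parameters.
#'
#' @param s Lag(s) in seconds, `t_post - t_pre` (vectorized).
#' @param params An [snn_params].
#' @return Window value(s), dimensionless.
#' @export
stdp_window <- function(s, params = snn_params()) {
  out <- numeric(length(s))
  pos <- s > 0
  neg <- s < 0
  out[pos] <- params$a_p * exp(-s[pos] / params$tau_p)
  out[neg] <- -params$a_d * exp(s[neg] / params$tau_d)
  out
}

# Sum of W over all (pre, post) pairs with |s| <= trunc; pre and post are
# sorted spike-time vectors. Windowed pairing via interval search, fully
# vectorized.
.pair_sum <- function(pre, post, params, trunc) {
  if (!length(pre) || !length(post)) return(0)
  i1 <- findInterval(post - trunc, pre) + 1L
  i2 <- findInterval(post + trunc, pre)
  n_k <- i2 - i1 + 1L
  keep <- n_k > 0L
  if (!any(keep)) return(0)
  idx <- sequence(n_k[keep], from = i1[keep])
  s <- rep.int(post[keep], n_k[keep]) - pre[idx]
  pos <- s > 0
  neg <- s < 0
  sum(params$a_p * exp(-s[pos] / params$tau_p)) -
    sum(params$a_d * exp(s[neg] / params$tau_d))
}

#' Pairwise STDP weight update
#'
#' Batch weight change over one learning interval:
#' `eta * (sum over pre/post pairs of W(t_post - t_pre) - b_j * N_pre)`,
#' with all pairs accumulated inside a `+/- 7 * max(tau_p, tau_d)`
#' truncation window. Pre-synaptic times should be synaptic arrival times
#' (axonal delay already added) when used inside the network.
#'
#' @param pre,post Sorted spike-time vectors (seconds).
#' @param params An [snn_params].
#' @param eta Learning rate (defaults to `params$eta`; training at desk
#'   scale passes the scaled rate).
#' @return The weight increment (scalar).
#' @export
stdp_delta <- function(pre, post, params = snn_params(), eta = params$eta) {
  trunc <- 7 * max(params$tau_p, params$tau_d)
  eta * (.pair_sum(pre, post, params, trunc) - params$b_j * length(pre))
}

#' Rate-based reduction of the STDP rule
#'
#' `alpha * (nu_i - nu_bar) * nu_j`: the mean-field limit of the pairwise
#' rule for statistically independent pre and post trains, with
#' `alpha = eta * T * integral(W)`. Serves as the analytic oracle for
#' [stdp_delta()] and makes the homeostatic fixed point at
#' `nu_i = nu_bar` explicit.
#'
#' @param nu_i Post-synaptic rate (spikes/s).
#' @param nu_j Pre-synaptic rate (spikes/s).
#' @param alpha Effective learning rate (negative for a net-depressing
#'   window).
#' @param nu_bar Target post-synaptic rate (spikes/s).
#' @return Weight increment (scalar, vectorized over rates).
#' @export
rate_based_delta <- function(nu_i, nu_j, alpha, nu_bar = 30) {
  if (any(nu_i < 0) || any(nu_j < 0)) stop("rates must be nonnegative")
  alpha * (nu_i - nu_bar) * nu_j
}

#' Train one pitch neuron on its own category
#'
#' Repeated 0.5 s presentations of the category's stimuli with fresh
#' Poisson draws; weights start uniform at `w0`, are frozen within each
#' presentation, updated between presentations via [stdp_delta()] per
#' channel (pre times taken at synaptic arrival, i.e. shifted by the
#' axonal delay) and clipped to the weight bounds. At desk scale the
#' learning rate is multiplied by `eta_scale` and the learning time
#' divided by `time_scale`; the product `eta * T` is preserved when the
#' two factors are equal, keeping the endpoint in the slow-learning
#' regime.
#'
#' @param envs List of `rate_envelope`s for this category (cycled over
#'   presentations).
#' @param params An [snn_params].
#' @param control An [snn_control()].
#' @param seed Integer master seed for this neuron's presentations.
#' @return List: `w` (final weights), `w_snapshot` (weights at the 10%
#'   point, the "initial stage" of learning), `trace` (data.frame with
#'   per-presentation output rate, mean absolute update and clip count).
#' @export
train_pitch_neuron <- function(envs, params = snn_params(),
                               control = snn_control(), seed = 1) {
  if (inherits(envs, "rate_envelope")) envs <- list(envs)
  nch <- nrow(envs[[1]]$lambda)
  pres_s <- envs[[1]]$duration_s
  n_pres <- max(1L, round(params$t_learn / control$time_scale / pres_s))
  eta_eff <- params$eta * control$eta_scale
  w <- rep(params$w0, nch)
  seeds <- .sub_seeds(seed, n_pres)
  snap_at <- max(1L, round(0.1 * n_pres))
  w_snapshot <- NULL
  trace <- data.frame(presentation = seq_len(n_pres), time_s = NA_real_,
                      rate = NA_real_, mean_abs_dw = NA_real_,
                      clipped = NA_integer_)
  trunc <- 7 * max(params$tau_p, params$tau_d)
  for (k in seq_len(n_pres)) {
    env <- envs[[(k - 1L) %% length(envs) + 1L]]
    trains <- poisson_spikes(env, seed = seeds[k])
    sim <- simulate_lif(w, trains, params, dt = control$dt,
                        duration = env$duration_s)
    post <- sim$trains[[1]]
    arr <- .arrival_times(trains, params$delay, env$duration_s)
    dw <- vapply(arr, function(a)
      eta_eff * (.pair_sum(a, post, params, trunc) -
                   params$b_j * length(a)), numeric(1))
    w_new <- w + dw
    clipped <- sum(w_new < params$w_min | w_new > params$w_max)
    w <- pmin(pmax(w_new, params$w_min), params$w_max)
    trace$time_s[k] <- k * pres_s * control$time_scale
    trace$rate[k] <- length(post) / env$duration_s
    trace$mean_abs_dw[k] <- mean(abs(dw))
    trace$clipped[k] <- clipped
    if (k == snap_at) w_snapshot <- w
  }
  list(w = w, w_snapshot = w_snapshot, trace = trace)
}

#' Average weight matrices across mixed-type runs
#'
#' Element-wise mean of equally-shaped weight matrices, as used to pool
#' repeated mixed-type training runs: type-specific spectral stripes
#' average out while the pitch-related structure, common to all runs, is
#' retained.
#'
#' @param runs List of numeric matrices of identical dimensions.
#' @return The element-wise mean matrix.
#' @export
mixed_type_average <- function(runs) {
  if (!length(runs)) stop("no runs to average")
  d <- dim(runs[[1]])
  if (!all(vapply(runs, function(m) identical(dim(m), d), logical(1))))
    stop("weight matrices must have identical dimensions")
  Reduce(`+`, runs) / length(runs)
}
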