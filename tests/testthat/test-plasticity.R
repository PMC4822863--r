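# STDP rule: learning-window analytics, pairwise updates against hand
# values and the rate-based mean-field oracle, homeostasis, bounds.

test_that("the learning window has the printed gains, decay and integral", {
  p <- snn_params()
  expect_equal(stdp_window(1e-9, p), 15, tolerance = 1e-5)
  expect_equal(stdp_window(-0.005, p), -10 * exp(-1), tolerance = 1e-12)
  expect_equal(stdp_window(0, p), 0)
  # closed form and numerical integration agree on int W = -0.035 s
  expect_equal(p$w_integral, -0.035)
  num <- stats::integrate(stdp_window, 0, 0.5, params = p,
                          rel.tol = 1e-10)$value +
    stats::integrate(stdp_window, -0.5, 0, params = p,
                     rel.tol = 1e-10)$value
  expect_equal(num, -0.035, tolerance = 1e-6)
  # wider extent towards depression
  dep <- -stats::integrate(stdp_window, -0.5, 0, params = p,
                           rel.tol = 1e-10)$value
  pot <- stats::integrate(stdp_window, 0, 0.5, params = p,
                          rel.tol = 1e-10)$value
  expect_equal(dep, 0.050, tolerance = 1e-6)
  expect_equal(pot, 0.015, tolerance = 1e-6)
  expect_gt(dep, pot)
})

test_that("pairwise updates match hand-computed values", {
  p <- snn_params()
  expect_equal(stdp_delta(numeric(0), numeric(0), p), 0)
  # one pre spike, no post: only the homeostatic term
  expect_equal(stdp_delta(0.1, numeric(0), p), -p$eta * p$b_j)
  expect_equal(stdp_delta(0.1, numeric(0), p), 1.05e-7, tolerance = 1e-12)
  # one causal pair at +1 ms: eta * (15 exp(-1) - b_j)
  expect_equal(stdp_delta(0.1, 0.101, p),
               p$eta * (15 * exp(-1) + 1.05), tolerance = 1e-12)
  expect_equal(stdp_delta(0.1, 0.101, p), 6.57e-7, tolerance = 1e-3)
  # anti-causal pair at -5 ms: depression branch
  expect_equal(stdp_delta(0.105, 0.1, p),
               p$eta * (-10 * exp(-1) + 1.05), tolerance = 1e-12)
  # pairs beyond the 7*tau_d truncation contribute only the rate term
  expect_equal(stdp_delta(0.1, 0.2, p), -p$eta * p$b_j)
})

test_that("the rate-based reduction has its fixed point at nu_bar", {
  expect_equal(rate_based_delta(30, 100, alpha = -1e-3), 0)
  expect_equal(rate_based_delta(80, 0, alpha = -1e-3), 0)
  alpha <- 1e-7 * 5000 * (-0.035)
  expect_lt(rate_based_delta(80, 100, alpha), 0)
  expect_gt(rate_based_delta(10, 100, alpha), 0)
  expect_error(rate_based_delta(-5, 10, alpha), "nonnegative")
})

test_that("pairwise STDP matches the mean-field oracle for independent trains", {
  p <- snn_params()
  T_ <- 100
  nu_j <- 100
  nu_i <- 80
  n_seeds <- 50
  deltas <- vapply(seq_len(n_seeds), function(s) {
    set.seed(700 + s)
    pre <- sort(stats::runif(stats::rpois(1, nu_j * T_), 0, T_))
    post <- sort(stats::runif(stats::rpois(1, nu_i * T_), 0, T_))
    stdp_delta(pre, post, p)
  }, numeric(1))
  expected <- p$eta * T_ * nu_j * (nu_i * p$w_integral - p$b_j)
  se <- stats::sd(deltas) / sqrt(n_seeds)
  expect_lt(abs(mean(deltas) - expected), 3 * se)
})

test_that("training is homeostatic from above and below the target rate", {
  ctl <- snn_control()
  env <- cached_env("tone", 220)
  # from above: w0 = 0.0075 starts near 80 spike/s
  above <- train_pitch_neuron(env, snn_params(), ctl, seed = 2)
  expect_gt(above$trace$rate[1], 45)
  expect_lt(abs(mean(utils::tail(above$trace$rate, 10)) - 30), 0.2 * 30)
  # from below: small w0 starts sub-threshold (rate < nu_bar)
  below <- train_pitch_neuron(env, snn_params(w0 = 0.003), ctl, seed = 7)
  expect_lt(below$trace$rate[1], 30)
  expect_lt(abs(mean(utils::tail(below$trace$rate, 10)) - 30), 0.25 * 30)
  # weights never leave their bounds; clipping is logged
  p <- snn_params()
  expect_true(all(above$w >= p$w_min & above$w <= p$w_max))
  expect_true(all(below$w >= p$w_min & below$w <= p$w_max))
  expect_true(is.numeric(above$trace$clipped))
})

test_that("training raises phase locking to the trained pitch", {
  p <- snn_params()
  fit <- cached_trained_110()
  env <- cached_env("tone", 110)
  vs_tr <- mean(vapply(1:5, function(s) {
    tr <- poisson_spikes(env, seed = 4000 + s)
    vector_strength(simulate_lif(fit$w, tr, p)$trains[[1]], 110)
  }, numeric(1)))
  vs_un <- mean(vapply(1:5, function(s) {
    tr <- poisson_spikes(env, seed = 4000 + s)
    vector_strength(simulate_lif(rep(p$w0, 200), tr, p)$trains[[1]], 110)
  }, numeric(1)))
  expect_gt(vs_tr, vs_un)
  expect_gt(vs_tr, 0.6)
})

test_that("endpoint is insensitive to the eta/T scaling split", {
  # same eta*T product, different granularity, small apical problem
  env20 <- calibrate_rates(
    auditory_periphery(pure_tone(220), cochlear_map(20, c(3, 12))),
    snn_control()$peak_rate)
  coarse <- train_pitch_neuron(env20, snn_params(),
                               snn_control(eta_scale = 250,
                                           time_scale = 250), seed = 3)
  fine <- train_pitch_neuron(env20, snn_params(),
                             snn_control(eta_scale = 100,
                                         time_scale = 100), seed = 3)
  r_coarse <- mean(utils::tail(coarse$trace$rate, 8))
  r_fine <- mean(utils::tail(fine$trace$rate, 20))
  expect_lt(abs(r_coarse - 30), 12)
  expect_lt(abs(r_fine - 30), 12)
  # endpoint weight profiles agree in shape
  expect_gt(stats::cor(coarse$w, fine$w), 0.5)
})

test_that("mixed-type averaging is the element-wise mean and reduces variance", {
  m1 <- matrix(1:6, 2)
  expect_equal(mixed_type_average(list(m1, m1)), m1)
  m2 <- matrix(seq(2, 12, by = 2), 2)
  expect_equal(mixed_type_average(list(m1, m2)), (m1 + m2) / 2)
  expect_error(mixed_type_average(list(m1, matrix(1:4, 2))), "identical")
  # averages of disjoint run pairs are closer than individual runs
  set.seed(9)
  runs <- lapply(1:4, function(i) matrix(0.01 + rnorm(40, sd = 0.003), 4))
  d_ind <- mean(utils::combn(4, 2, function(ij)
    sqrt(mean((runs[[ij[1]]] - runs[[ij[2]]])^2))))
  d_avg <- sqrt(mean((mixed_type_average(runs[1:2]) -
                        mixed_type_average(runs[3:4]))^2))
  expect_lt(d_avg, d_ind)
})
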