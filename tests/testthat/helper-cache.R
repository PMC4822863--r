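# Shared, lazily-built objects reused across test files. Everything is
# seeded, so caching only avoids recomputation, not randomness.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# full-resolution (200-channel) rate envelope for a standard stimulus
cached_env <- function(type = "tone", pitch = 110) {
  key <- sprintf("env_%s_%g", type, pitch)
  cached(key, {
    ctl <- snn_control()
    stm <- auditory_periphery(pitchsnn:::.category_wave(type, pitch),
                              cochlear_map())
    calibrate_rates(stm, ctl$peak_rate, ctl$sat_frac)
  })
}

# one pitch neuron trained on 110 Hz pure tones at the standard desk scale
cached_trained_110 <- function() {
  cached("trained_110",
         train_pitch_neuron(cached_env("tone", 110), snn_params(),
                            snn_control(), seed = 1))
}

# miniature fixture model (3 pitch categories, 20 channels)
cached_fixture <- function() cached("fixture", pitch_fixture(seed = 1))

# regular spike train helper
regular_train <- function(period_s, duration_s, t0 = period_s) {
  seq(t0, duration_s, by = period_s)
}
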