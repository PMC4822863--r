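Package: pitchsnn
Title: Place and Temporal Pitch Codes from a Plastic Spiking Auditory Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-phase spiking-network model of pitch perception. Phase I is a
    simplified auditory periphery (middle-ear filter, 200-channel gammatone
    filterbank at Greenwood characteristic frequencies, inner-hair-cell
    transduction) that converts calibrated sound waveforms into
    spatio-temporal activity maps and place codes of pitch. Phase II converts
    the maps into inhomogeneous Poisson auditory-nerve spike trains that
    drive a layer of conductance-based leaky integrate-and-fire pitch
    neurons whose synapses are trained by an asymmetric, rate-stabilised
    spike-timing-dependent plasticity rule. Temporal pitch codes are read
    out as vector-strength matrices and pooled inter-spike-interval
    histograms, and evaluated with a perceptron pitch-ranking experiment,
    including missing-fundamental (high-pass "telephone") conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    Matrix,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
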