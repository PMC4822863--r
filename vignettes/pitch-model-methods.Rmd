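---
title: "A spiking-network model of place and temporal pitch codes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking-network model of place and temporal pitch codes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pitchsnn)
```

## The model in one paragraph

Pitch information travels in two codes. The *place code* is the profile of
time-averaged activity across tonotopically ordered auditory-nerve
channels; it follows the spectral envelope of the sound and therefore
confounds pitch with timbre, and it collapses when the fundamental is
filtered out (the "telephone" condition). The *temporal code* lives in
spike timing: phase locking to the stimulus period and the distribution
of inter-spike intervals. `pitchsnn` implements a two-phase model of how
a temporal pitch code can *develop*: Phase I converts sound into
spatio-temporal activity maps (and place codes); Phase II converts the
maps into Poisson spike trains that drive a layer of 29 conductance-based
leaky integrate-and-fire (LIF) "pitch neurons" — one per semitone of the
[98, 493] Hz ladder — whose 200 afferent synapses are shaped by an
asymmetric, homeostatic spike-timing-dependent plasticity (STDP) rule.
After unsupervised exposure to sounds of its own pitch category, each
neuron fires sparsely and in phase with its pitch period; pooled
inter-spike-interval histograms (ISIHs) then carry pitch through their
dominant interval, robustly across spectral shapes and without the
fundamental.

## Phase I: stimuli and periphery

**Stimuli.** All standard stimuli are 0.5 s, 16 kHz, 60 dB SPL: pure
tones on the 29-note equal-tempered ladder, sustained vowels /a/
(formants 710/1150/2700 Hz, bandwidths 40/43/105 Hz) and /i/
(230/2000/3000 Hz, 68/63/129 Hz) synthesized as an impulse train through
cascaded second-order resonators, and "telephone" variants passed through
a high-pass filter with stop band at and below 300 Hz (≥ 80 dB
attenuation) and pass band at and above 350 Hz (≤ 1 dB ripple). The
printed pitch range [98, 493] Hz is interpreted as G2–B4; the 29th note
is 98·2^(28/12) ≈ 493.9 Hz. Levels follow a documented convention —
a full-scale sinusoid is 94 dB SPL — whose absolute scale is absorbed by
the spike-rate calibration below. The vowel source is a plain impulse
train with no amplitude ramp; no glottal-pulse shaping or parallel
synthesis branch is modelled, since only the resulting spectro-temporal
structure feeds the model.

The published band specification for the telephone filter cannot be met
by a short FIR: a 50 Hz transition with 80 dB stop-band attenuation at
16 kHz requires on the order of 1600 taps by the standard Kaiser/Harris
order estimates. We use a Kaiser-window high-pass FIR (1801 taps,
β ≈ 7.86, cutoff 325 Hz) that meets the band specification with margin
(measured −88 dB at 300 Hz), applied non-causally (filter-then-trim)
so filtered and unfiltered stimuli stay sample-aligned.

**Periphery.** A first-order 0.1–6 kHz band-pass stands in for the
middle ear. The cochlea is a bank of 200 fourth-order gammatone filters
with equivalent-rectangular-bandwidth-scaled bandwidths, centered at the
Greenwood characteristic frequencies of positions 3–22.9 mm (0.1 mm
steps), CF(d) = 165.4·(10^(2.1·d/34) − 1), i.e. ~88 Hz to ~4.1 kHz.
Inner-hair-cell transduction is half-wave rectification followed by a
second-order 1 kHz Butterworth low-pass. This is deliberately simpler
than a phenomenological cochlear model — no compression, suppression or
adaptation — and is the largest fidelity gap of the package: it
preserves what Phase II consumes (tonotopy, phase locking, formant
peaks, travelling-wave-like group delays) and nothing more. The *place
code* is each channel's mean activity over a 100 ms window, normalized
to maximum; the first 50 ms are skipped to avoid filter onset
transients (the placement of the averaging window within the 0.5 s
stimulus is otherwise immaterial for sustained sounds).

## Phase II: spikes, neurons, plasticity

**Spike generation.** Each channel's activity is read as the intensity
λ_j(t) of an inhomogeneous Poisson process (exact thinning against the
piecewise-constant envelope at the audio sample resolution). No
refractoriness is imposed here; it lives in the output-neuron model.
Activity maps to intensity through a saturating (Michaelis–Menten)
transduction, λ = peak_rate·a/(a + a50) with a50 = `sat_frac` of the
map's maximum — the auditory nerve's normal operating regime at
conversational levels. Saturation matters structurally, not just
physiologically: it bounds the rate any one channel can carry, so the
drive a stimulus delivers is spread over many afferents. In a linear
calibration the spectral-peak channel carries the entire calibrated
intensity, and a pitch neuron with a single plasticity-saturated flank
weight at that channel bursts at hundreds of spikes/s to foreign
stimuli, swamping every pooled readout; under saturation foreign
responses drop to near zero while the within-period phase modulation —
what the plasticity feeds on — survives, because the half-wave-rectified
envelope still passes through zero each cycle. The two constants
(`peak_rate = 2000` spikes/s, `sat_frac = 0.01`; a channel abstracts a
small population of fibers) were fixed by a one-off sweep so that an
untrained output neuron with uniform initial weights w0 = 0.0075 fires
in the high initial regime (~80 spike/s on mid-ladder tones) that makes
early plasticity fast; they live in `snn_control()` and are never
hard-coded in algorithms.

**Output neurons.** Each of the 29 pitch neurons obeys the
conductance-based LIF equation
dV/dt = (V_p − V + Σ_j w_j g_j(t) (V_rev − V)) / τ_m with τ_m = 10 ms,
V_p = V_r = −65 mV, V_th = −50 mV, V_rev = 0 mV, absolute refractory
period 1 ms (V clamped at V_r; conductances keep evolving), and a
common 10 ms axonal delay on all afferents. g_j is the
double-exponential EPSC kernel (rise 0.5 ms, decay 1 ms) summed over
the delayed afferent spikes. The kernel is unit-normalized on the
millisecond timescale (integral 10⁻³ s): this is the scale on which the
printed weight values are meaningful — with a unit-second integral a
single afferent spike at w0 would depolarize the cell by ~50 mV and
fire it, leaving no summation regime. Integration is exponential Euler
at dt = 0.1 ms on the linear-in-V form, with the kernel tracked as two
exponential state variables (exact for impulse inputs on the step
grid); spike times are therefore quantized to dt, and halving dt moves
spikes by at most one coarse step. Negative weights (the lower bound is
−0.2) sit oddly beside the statement that all inputs are excitatory;
both readings are implemented in `simulate_lif()` — the default takes
the equation literally (negative efficacies hyperpolarize), and a
clip-at-zero mode treats the lower bound as a brake on depression
only.

**Plasticity.** The learning window is
W(s) = A_p e^(−s/τ_p) for s > 0 and −A_d e^(s/τ_d) for s < 0, with
s = t_post − t_pre, A_p = 15, τ_p = 1 ms, A_d = 10, τ_d = 5 ms — an
asymmetric window with a wider extent towards depression whose integral
is A_p τ_p − A_d τ_d = −0.035 s. (The printed potentiation branch with
a positive exponent diverges and contradicts this integral; the
decaying form is the only consistent reading.) Weight updates are
batched per 0.5 s presentation: Δw_j = η (Σ_pairs W(t_post − t_arr) −
b_j N_pre), all pairs within ±7·τ_d, with arrival (synaptic) rather
than emission times driving the pairing, b_j = ν̄·∫W = −1.05 and
η = 10⁻⁷. For uncorrelated trains the rule reduces to the rate law
Δw = α(ν_i − ν̄)ν_j with α = ηT∫W < 0, which pins the output rate at
ν̄ = 30 spike/s; the correlational term selects synapses whose arrival
phase leads the output spikes, producing phase locking. Weights are
clipped to [−0.2, 0.2] and clip counts logged.

**Desk scale.** The published schedule (T = 5000 s per category) is
cluster-scale. The default configuration multiplies η by 100 and
divides T by 100 (100 presentations per category), preserving the η·T
product; in the slow-learning regime the endpoint is insensitive to the
split, which the test suite checks by comparing a ×250/÷250 against a
×100/÷100 run. Per-presentation updates are coarser at desk scale, so
rate traces oscillate more than a full run would; the asymptote is
unchanged (measured 24–35 spike/s over nine seed/pitch combinations).
Full-paper scaling is `snn_control(eta_scale = 1, time_scale = 1)`.

## Reading out the temporal code

*Vector strength* is the Goldberg–Brown resultant
|Σ e^(2πi f t_k)|/N with phase referenced to stimulus onset; 5 s
analysis intervals are realized as 10 half-second presentations with
fresh Poisson draws, each presentation contributing phases referenced
to its own onset (the stimulus restarts). *Pooled ISIHs* use
consecutive (first-order) intervals within presentations only, pooled
across the 29 neurons, in 1 ms bins over 0–50 ms, smoothed with a
span-3 moving average (endpoint windows shrink to the sample, as a
padded edge would double-count its neighbour) and normalized to
maximum;
an all-order option exists for comparison with all-interval analyses.
The *dominant interval* (maximal smoothed bin, ties to the shorter
interval) is the temporal pitch estimate; `isih_peak_spacing()` reads
the period as the median spacing of histogram peaks at ≥ 25% relative
height, which is the more robust readout when the dominant bin falls on
a period multiple.

*Pitch ranking* feeds pairs of smoothed 50-bin ISIHs (concatenated:
100 inputs) to two linear output units with softmax, trained by the
delta rule (back-propagation collapsed to a single layer) with early
stopping on a 10% validation split (max 500 epochs, step 0.1). Only
same-type vowel pairs 1–12 semitones apart are eligible; per trial the
eligible pair set is split 75/25 into disjoint train/test pools, 1500
training and 500 test pairs are drawn with replacement, and scores are
averaged over 20 trials. Chance is 50%.

## What the synthetic data does and does not show

All inputs are synthesized under the stated study conditions (0.5 s,
16 kHz, 60 dB SPL, the 29-note ladder, the two vowel specifications and
their telephone variants); instrument recordings can be supplied as WAV
files but nothing depends on them. The generator emulates periodicity,
formant structure and missing-fundamental spectra. It does not emulate
level roving, background noise, reverberation, auditory-nerve
adaptation or fiber-class diversity — passing tests therefore show that
the learning rule extracts periodicity under clean, stationary
conditions, not that it would survive realistic acoustics.

Three deliberate design readings are worth knowing about. First,
repeated mixed-type training is summarized by averaging the *dynamics*,
not by simulating the averaged weight matrix: different runs rail
different synapses against the bounds, and the spiking threshold does
not commute with averaging — the element-wise mean of five run matrices
is typically sub-threshold and silent. `pitch_snn(runs = 5)` therefore
keeps the five member fits and `simulate()` rotates presentations over
them, so every pooled readout (vector strength, ISIHs, ranking pools)
pools responses across runs; the averaged matrix itself is still
computed for inspecting the run-invariant connectivity pattern. Second,
low-CF suppression in the telephone place code is checked *relative* to
the unfiltered vowel (≥ 5× below 250 Hz): an absolute criterion is
unattainable next to the cutoff because the filter legitimately passes
the 330 Hz harmonic of a 110 Hz voice, which any realistic cochlear
bandwidth maps into channels just below 300 Hz. Third, pooled ISIHs
include all 29 pitch neurons, matched or not, exactly as the pooled
readout demands; the saturating transduction is what keeps mismatched
neurons quiet enough for the dominant interval to track the period.

## Numerical choices and problem sizes

- LIF integration: exponential Euler, dt = 0.1 ms (hard upper limit);
  convergence checked by dt-halving.
- Poisson thinning is exact for the sampled envelope; all randomness
  flows from one master seed through deterministically expanded
  sub-seeds (31-bit), so every fit, simulation and experiment is
  reproducible.
- STDP pair accumulation truncates at |s| > 35 ms (7·τ_d); the
  truncated tail contributes < 10⁻³ of the window mass.
- The test suite trains the five-run mixed-type ensemble once at desk
  scale (200-channel periphery, 100 presentations per category per run)
  and reuses it across the structural checks; the miniature fixture (3
  categories, 24 apical channels over 3–12 mm) exists because a
  20-channel full-range map spaces channels several ERBs apart, which
  makes desk-scale updates bang-bang and convergence unreliable —
  a coarse map is a legitimate failure mode, not a bug.
- Exact-millisecond intervals sit on ISIH bin edges; tests treat either
  adjacent bin as correct.

## Known limitations

The periphery omits level-dependent compression and adaptation, so
place codes are more linear in level than real rate profiles.
Homeostasis is enforced per category during training; responses to
*foreign* stimuli are not rate-controlled, and the pooled ISIH inherits
that noise. Mixed-type training draws from tones and the two vowels
(no instrument corpus), and the ranking experiment reuses one histogram
per (type, pitch) rather than resampling response noise per pair.

Two limits are structural rather than incidental, and the acceptance
suite reports them honestly. The dominant pooled interval equals the
pitch period only over roughly the lower two-thirds of the ladder: a
neuron homeostatically pinned at ~30 spike/s with a 10 ms membrane
time constant cannot fire in consecutive 2–4 ms periods, so for high
pitches the modal interval sits at a period *multiple* — under any
interval order (first- or all-order) and any training mode. The
shorter-intervals-for-higher-pitch trend still holds. And while
high-pass-filtered (telephone) vowels rank well above chance with the
same rising-with-interval profile — the temporal code does survive the
missing fundamental — their scores sit measurably below the unfiltered
pool here: the mixed-trained neurons exploit low-CF fine structure more
effectively than the mid-CF envelope beats that carry F0 after
filtering.
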