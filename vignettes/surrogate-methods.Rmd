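---
title: "Convolutional surrogates of auditory sensory cells and synapses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolutional surrogates of auditory sensory cells and synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(periphnet)
```

## The problem

Mechanistic models of the auditory periphery — inner-hair-cell (IHC)
transduction, the IHC–auditory-nerve-fiber (ANF) synapse, Hodgkin–Huxley (HH)
style neurons — are sets of coupled non-linear ODEs. They are accurate but
slow, hard to parallelise, and, critically, not differentiable end to end, so
they cannot sit inside optimisation loops that backpropagate through the
periphery (closed-loop stimulus design, hearing-restoration processing,
large-scale network models).

`periphnet` implements a hybrid approach: an analytical "teacher" model
generates a large stimulus–response corpus, and a convolutional
encoder–decoder network ("surrogate") is trained to reproduce the teacher's
input–output transformation sample by sample. The surrogate is a chain of
strided 1-D convolutions — fast, parallel over time and tonotopic channels,
and differentiable, so gradients can be pushed through it back to the
stimulus.

## The surrogate architecture

A surrogate is described by a `surrogate_spec()`: an output window of `L`
samples flanked by `L_l` left and `L_r` right context samples (input window
`L_c = L_l + L + L_r`), an even total layer count `n_total`, a per-layer
filter count, a filter length, and the activation functions. The encoder is
`N = n_total/2` stride-2 convolutions (halving the temporal dimension each
layer, so `L_c` must be divisible by `2^N`); the decoder mirrors it with
stride-2 transposed convolutions (doubling each layer). Skip connections
concatenate each encoder layer's post-activation output onto the
corresponding decoder layer's input to preserve stimulus phase through the
bottleneck; decoder layer 1 receives the bottleneck alone, and the final
decoder layer maps to one output channel with no activation. A cropping step
removes the context, so the network emits exactly `L` samples.

Two details of the skip wiring are not forced by the drawing of such
architectures and were fixed by parameter accounting: (i) skips concatenate
(rather than add) channels, so decoder layers 2..N see `2F` input channels,
and (ii) every convolution carries a bias. With those choices the closed-form
count

```
encoder: (kF + F) + (N-1)(kF^2 + F)
decoder: (kF^2 + F) + (N-2)(2kF^2 + F) + (2kF + 1)
PReLU:   + F per layer except the last
```

reproduces the reference totals of the four preset architectures exactly
(1,317,505 / 1,248,449 / 1,250,177 / 1,250,177; 5,066,308 merged), which is
how the wiring was validated (`count_trainable_params()` versus
`introspect_params()`). Whether skips tap pre- or post-activation encoder
outputs cannot be distinguished by counting; post-activation was chosen.

Transposed convolutions are implemented as the exact adjoint of the forward
convolution's gather (padding `k - 2`, split left-symmetrically), which
guarantees the exact 2x length doubling and makes the backward pass a mirror
image of the forward pass. Weights initialise uniformly in
`±sqrt(1/(k·C_in))` under a seed; biases (and the training loop, validation
split and shuffling) are likewise seeded, so training is bitwise
reproducible.

Because one set of single-channel weights is learned, a trained surrogate
applies to any number of tonotopic channels (`surrogate_predict()` treats
channels as a batch): identical channels produce bitwise-identical outputs
and channel permutation is an exact equivariance.

## Receptive-field design rules

One unit after `N` stride-2 layers of filter length `k` sees
`r_N = (k-1)(2^N - 1) + 1` input samples (`receptive_field()`). The design
rule implemented by `advise_architecture()` is: measure the teacher's
adaptation time course (`estimate_adaptation_time()`: the time for the
response envelope to enter and stay within ±5% of the steady state, the
steady state being the mean of the final 10% of the stimulated segment),
convert it to samples, and pick the smallest `N` whose receptive field
*strictly exceeds* that target (`min_encoder_layers()`). Strict inequality is
the reading consistent with the reference worked examples (a 16,384-sample
window needs 12 encoder layers at `k = 8`; a 750-sample adaptation course
needs 6 layers at `k = 16` or 3 at `k = 128`). The closed form is
cross-checked in the tests by a brute-force oracle that backpropagates a unit
gradient from one centred bottleneck unit of a randomly initialised encoder
and counts the non-zero support in the input.

## The analytical teachers

The full reference periphery model this framework was developed around lives
in an external repository; `periphnet` ships documented desk-scale stand-ins
behind a uniform interface so every pipeline stage is testable end to end.
The stand-in equations and constants are the package's own and are printed in
the function documentation:

* **Basilar-membrane stage** (`bm_drive()`): per CF, a zero-phase asymmetric
  log-Gaussian bandpass (half-widths 1.2 octaves below CF, 0.35 above — the
  shallow low-frequency tail of cochlear filters), then broken-stick
  compression of displacement (knee 2.7e-7, exponent 0.4, linear gain
  3e-4 displacement units per Pa). Saturation of on-CF channels plus the
  shallow tail produce the level-dependent basal-ward shift of excitation
  maxima. The displacement scale is a stand-in unit: it is chosen, together
  with the IHC Boltzmann constants below, so that the x1e6 stage scaling
  lands the training inputs near unit variance — the stated purpose of the
  stage scalings — rather than to match physiological nanometre values.
* **IHC transduction** (`simulate_ihc()`): a Boltzmann open-probability
  `g(u) = 1/(1+exp(-(u-x0)/s0))` with an offset operating point
  (`x0` = 1.2e-6, `s0` = 1e-6 in the same displacement units) so depolarising deflections dominate — this
  rectification is the source of the DC receptor potential — followed by a
  first-order membrane low-pass at 650 Hz. The basal shunt is solved so the
  resting potential is exactly −57 mV. The low-pass makes the AC/DC ratio
  fall with frequency above ~600–700 Hz, the signature the AC/DC metric
  probes.
* **ANF synapse** (`simulate_anf()`): a three-store diffusion system — free
  transmitter pool `q`, cleft `c`, reprocessing store `w` — with release
  `k(V)·q` driven by a saturating Boltzmann function of the receptor
  potential, cleft loss and reuptake, reprocessing return, and factory
  replenishment `y(M-q)`. The instantaneous rate is `h·c`. The gain `h` is
  solved in closed form from the silent steady state so each preset's
  spontaneous rate is met by construction (68.5 / 10 / 1 spikes/s for the
  high-/medium-/low-SR fibers), and integration starts at that steady state.
  The release-function steepness and offset differentiate the fiber classes:
  the HSR preset saturates within a few mV of rest (sharp rate-saturation,
  low threshold), the LSR preset sits far from its half-activation point
  (sloping, non-saturating rate-level growth, high threshold, strong
  envelope synchrony). Store depletion gives onset adaptation with a
  dominant time constant `1/(k_max + y)` ≈ 60 ms, and replenishment gives
  onset-peak recovery over hundreds of milliseconds.
* **Hodgkin–Huxley axon** (`simulate_hh()`): the classical squid-axon
  four-state model with the standard coefficients (gNa 120, gK 36, gL 0.3
  mS/cm², ENa 50, EK −77, EL −54.387 mV), exponential-Euler gates and
  forward-Euler voltage at 100 kHz. The test suite integrates the same
  equations independently with `deSolve::lsoda` as an oracle.

Numerical choices: all teachers integrate at a fixed 100 kHz solver rate
(`SOLVE_FS`). The synapse uses forward Euler applied flux-by-flux so the
store budget residual is exactly zero up to float rounding (the largest rate
constant, ~9e3/s, leaves a stability margin of ~20x at dt = 1e-5 s). The
IHC membrane filter is a one-pole recursive filter. Envelopes for
adaptation-time estimation use the analytic-signal magnitude for oscillatory
responses and the raw trace for rates.

Two reference-model behaviours are deliberately only direction checks on the
stand-ins, because the reference percentages are properties of the external
model: (i) onset-peak recovery versus interstimulus interval is required to
be non-decreasing with value 1 at 1.9 s (the stand-ins recover somewhat
faster and shallower than the reference model's 92–96% at 0.4 s); (ii) the
steady-state fraction at 0.4 s. On (ii), note that the reference low-SR
fiber *builds up* towards its steady rate (fraction < 1) whereas a
three-store system always decays towards it from the onset peak
(fraction ≥ 1); the implemented direction check is therefore that the
high-SR fiber is *closer to* its steady state at 0.4 s than the low-SR
fiber, which is the substance of the reference ordering.

## Data conventions

The training pipeline (`build_training_set()`) mirrors the reference
conventions: teachers run at 100 kHz; outputs are resampled to the 20 kHz
surrogate rate with a zero-phase Kaiser-windowed FIR anti-aliasing filter
(~80 dB stopband, passband loss < 0.1 dB — the filter itself is a design
choice, checked by spectral tests); stage scalings ×1e6 (BM, m → µm), ×10
(IHC, V → dV) and ×1e-2 (ANF, spikes/s → 100 spikes/s) bring every stage
near unit scale; synapse-stage sequences get 0.5 s leading and 1 s trailing
silence so recovery from silence is in the data (the IHC stage does not —
membrane adaptation is milliseconds, so the windows' own context suffices);
sequences are sliced into 50%-overlap windows with zero-filled context
beyond the signal edges (the analytical responses start from silence, so
zero-fill is the consistent edge policy); and CF channels are flattened into
independent single-channel sequences, because the IHC/ANF parameters are
CF-independent (2310 items × 201 CFs → 464,310 sequences). The 201-CF axis
is uniform in the Greenwood place coordinate of the human cochlea
(`f(x) = 165.4·(10^{2.1x} − 0.88)` Hz — the standard human constants, which
the place-frequency description leaves implicit), with endpoints solved to
hit 112 Hz and 12 kHz exactly.

## Training

Surrogates minimise the mean absolute error (L1) between the cropped network
output and the teacher target, with Adam. The reference configuration uses a
learning rate of 1e-4; the desk-scale runs in this package use 1e-3 with a
×0.3 step decay every 40 epochs, which reaches the same loss floor in
minutes instead of hours at these problem sizes. Epoch count and batch size
are not prescribed by the reference procedure, so the trainer supports early
stopping on a seeded 90/10 validation split (patience configurable) and
always returns the best-validation checkpoint; divergence aborts with the
last good checkpoint. Two runs with the same seed produce identical loss
histories.

## The synthetic speech-like corpus

Training material is a seeded synthetic corpus (`speech_like_corpus()`)
standing in for a recorded speech corpus: pink-weighted noise in 8
log-spaced bands, each with an independent 2–10 Hz envelope (the syllabic
modulation range of speech), summed and RMS-calibrated — half the items to
70 dB SPL and half to 130 dB SPL, the two-level scheme that exposes the
saturation properties of IHC and ANF processing to the learner. The corpus
reproduces the broadband, slow-modulated, two-level statistics that the
training set needs; it does **not** contain phonetic structure, harmonic
voicing, or speech-specific spectro-temporal correlations, so passing tests
demonstrate surrogate recovery of the teacher's transformation under
realistic signal statistics, not performance on real speech.

## Evaluation metrics

Six classical electrophysiology paradigms, implemented as pure functions of
a model handle (`periph_model`) so teachers and surrogates are measured
identically; stimuli are built with Eq.-style calibration against
p0 = 2e-5 Pa and metric-specific ramps (5 ms for tones, 7.8 ms for SAM
tones, 2.5 ms for rate-level tones):

1. **Excitation patterns** — mean depolarisation across CF for 0.5/1/2-kHz
   tones, 10–90 dB SPL. The tone duration is not prescribed; the
   implementation fills the evaluation window after the leading silence.
2. **AC/DC ratio** — 80-ms, 80-dB tone bursts; AC is the RMS of the
   mean-subtracted 50–70-ms steady-state segment and DC the steady mean
   minus the resting mean 5–15 ms before onset. ("RMS of the AC component,
   defined as the sinusoidal amplitude" is ambiguous between amplitude and
   RMS; the RMS convention is used consistently for both models so ratios
   stay comparable.)
3. **Potential-level growth** — half-wave-rectified RMS of the 4-kHz
   steady-state response versus level; "subtracting the DC component" is
   read as subtracting the steady-state mean, not the resting potential.
4. **ANF firing rates** — rate traces for 1/4-kHz tone and SAM-tone bursts
   at 70 dB SPL (phase-locking present at 1 kHz, absent at 4 kHz).
5. **Rate-level curves** — mean rate 10–40 ms after onset, 50-ms tones at
   1007 / 3972.7 Hz.
6. **Synchrony-level curves** — vector strength `|F(fm)|/|F(0)|` of the rate
   trace for fully modulated 400-ms SAM tones. Whether the onset is included
   is unspecified; the implementation uses the steady portion from 100 ms
   after onset (an integer number of modulation periods) to avoid onset
   bias.

Evaluation stimuli carry ~20 ms of leading silence so the resting-potential
window exists, mirroring the context-silence convention of the reference
evaluation containers.

## Desk-scale study conditions

Full-scale training (window 2048/16384, 128/64 filters, hundreds of
thousands of windows) runs for days and is supported but not exercised by
the tests. The shipped desk-scale conditions, chosen once, are: a 6-item,
1-s corpus at the standard 70/130 dB split, 3 CFs (0.5/1/2 kHz), 384
training windows, and the reduced IHC geometry `L 512, contexts 64/64, 6
layers, 32 filters, kernel 16` (the reference IHC architecture scaled to
minutes of CPU time; its 5.3-ms receptive field still exceeds the IHC
stand-in's millisecond-scale adaptation). The surrogate-recovery check
requires held-out pure-tone responses (never in the training corpus) to
reach a relative RMSE — RMSE divided by the RMS of the teacher response —
below 10%, and the AC/DC ratio of the surrogate to decline across 0.5/1/2
kHz as the teacher's does. The backpropagation demonstration merges the desk
IHC surrogate with a shallow desk ANF surrogate (window 512, contexts
448/64, 10 layers, 16 filters, kernel 8), scales the population rate by 10
(normal innervation) versus 8 (20% deafferentation), and trains a small
preprocessor through the frozen pathological chain to minimise the L1
distance of time traces plus magnitude spectra; success is a restored loss
below the unprocessed baseline.

## Known limitations

* The teachers are stand-ins: they reproduce the *kinds* of behaviour the
  metrics probe (rectification, phase-locking loss, adaptation, recovery,
  SR-dependent rate-level shapes), not the reference model's numerical
  curves; the reference model's error panels and percentage figures are
  out of reach by construction.
* The desk-scale surrogate reproduces small DC components of the receptor
  potential with limited relative accuracy (they sit near its L1 loss
  floor); the AC/DC check is therefore a direction check, not a magnitude
  match.
* Surrogates extrapolate poorly outside the amplitude statistics of their
  training corpus, exactly as the data-driven character of such models
  predicts; the metric suite deliberately probes unseen stimulus classes but
  stays within the trained level range.
* Stochastic vesicle release and spike generation are out of scope; all
  rates are mean instantaneous rates.
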