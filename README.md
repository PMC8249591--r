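# periphnet

Convolutional encoder–decoder surrogates of auditory sensory-cell and
synapse models, in R.

## What this is for

Mechanistic models of the auditory periphery — inner-hair-cell (IHC)
transduction, the three-store diffusion model of the IHC–auditory-nerve-fiber
(ANF) synapse, Hodgkin–Huxley (HH) neurons — are coupled non-linear ODE
systems: accurate, but slow and not differentiable, which keeps them out of
backpropagation-based applications (closed-loop stimulus optimisation,
model-based hearing-restoration processing, large network simulations).

`periphnet` implements the hybrid alternative for computational
neuroscientists and hearing researchers: analytical "teacher" models generate
a large seeded stimulus–response corpus, and a strided 1-D convolutional
encoder–decoder ("surrogate") is trained to reproduce the teacher's
transformation. The surrogate of an encoder depth `N`, filter length `k` and
stride 2 has receptive field

```
r_N = sum_{n=1..N} (k-1)·2^(n-1) + 1  =  (k-1)(2^N - 1) + 1
```

and the core design rule is to choose `(N, k)` so that `r_N` exceeds the
teacher's adaptation time course. Trained surrogates are CF-agnostic (one set
of single-channel weights applies to any number of tonotopic channels), can
be merged across stages into a differentiable periphery, and are evaluated
with six classical electrophysiology metrics: excitation patterns, AC/DC
ratio, potential-level growth, firing rates, rate-level curves and
synchrony-level (vector-strength) curves.

Everything is in the package: calibrated stimulus generators (pure tones, SAM
tones, tone pairs, step currents, a seeded speech-like corpus at 70/130 dB
SPL), desk-scale analytical teachers (BM stage, Boltzmann + low-pass IHC,
three-store synapse with 68.5/10/1 spikes/s fiber presets, classical HH
axon), the network engine with hand-rolled backpropagation and Adam, the
dataset conventions (100 kHz → 20 kHz resampling, ×1e6/×10/×1e-2 stage
scalings, 50%-overlap context windows, CF flattening, Greenwood CF axis), the
metric suite, and a backpropagation demo that restores a deafferented (×8
fibers) population response toward the normal (×10) one.

## Worked example

Receptive-field design, teacher simulation, and a desk-scale training run:

```r
library(periphnet)

# How deep must an encoder be to cover a 16,384-sample window with kernel 8?
min_encoder_layers(16384, kernel = 8)      # 12
receptive_field(12, 8)                     # 28666 samples
advise_architecture(0.0375, fs = 2e4, kernel_options = c(16, 128))
#   kernel n_layers  rf rf_ms   L
# 1     16        6 946  47.3 768
# 2    128        3 890  44.5 752

# The reference architectures and their exact parameter counts
sp <- preset_specs()
count_trainable_params(sp$ihc)             # 1317505
count_trainable_params(sp$anf_h)           # 1250177
sum(sapply(sp, count_trainable_params))    # 5066308

# Fiber presets hold their spontaneous rates from silence, by construction
silence <- response_field(rep(ihc_params()$v_rest, 1e5), 1e5, 1000, "V")
mean(simulate_anf(silence, fiber_preset("hsr"))$values[50001:1e5, 1])  # 68.5

# Desk-scale surrogate training against the IHC stand-in
corpus <- speech_like_corpus(6, 1.0, SOLVE_FS, seed = 42)
ws  <- build_training_set(corpus, "ihc", desk_specs()$ihc,
                          cf_axis = c(500, 1000, 2000), max_windows = 384)
res <- train_surrogate(desk_specs()$ihc, ws,
                       train_config(learning_rate = 1e-3, epochs = 120,
                                    batch_size = 32, seed = 7,
                                    lr_decay = 0.3, decay_every = 40))
min(res$history$val_loss)                  # 0.00166 (dV units)

# Evaluate the surrogate exactly as the teacher
sm <- wrap_surrogate_model(res$model, "ihc", c(500, 1000, 2000))
tm <- wrap_teacher_model("ihc", c(500, 1000, 2000))
ac_dc_ratio(sm, freqs = c(500, 1000, 2000))$y   # 6.75 4.49 2.98
ac_dc_ratio(tm, freqs = c(500, 1000, 2000))$y   # 5.79 4.02 2.28
```

The validation loss is the mean absolute error in scaled receptor-potential
units (1 dV = 0.1 V); 0.00166 dV means the surrogate tracks the teacher's
receptor potential to within ~0.2 mV on held-out windows, a relative RMSE of
about 1% on held-out tone responses. The AC/DC ratio —
oscillatory over sustained receptor-potential component, the classical index
of IHC phase-locking — declines with frequency for both teacher and
surrogate, reflecting the IHC membrane low-pass.

A command-line front end wrapping these functions (subcommands `design`,
`corpus`, `dataset`, `train`, `evaluate`, `demo-backprop`) is installed at
`inst/cli/periphnet.R`:

```sh
Rscript inst/cli/periphnet.R design --adaptation-ms 37.5 --fs 20000 --kernels 16,128
```

## Package layout

- `R/stimuli.R` — calibrated stimulus generators, WAV I/O, speech-like corpus
- `R/reference_models.R` — BM/IHC/ANF stand-ins, HH axon, adaptation metrics
- `src/integrators.cpp` — fixed-step HH and three-store synapse cores
- `R/rf_design.R` — receptive-field arithmetic and the architecture advisor
- `R/network.R`, `R/architecture.R` — the conv engine, specs, presets,
  parameter accounting, merging, channel extrapolation
- `R/datasets.R` — resampling, scalings, silence, windowing, CF flattening
- `R/training.R` — L1/Adam trainer, stimulus-preprocessor backprop demo
- `R/evaluation.R` — the six metrics and the evaluation report
- `vignettes/surrogate-methods.Rmd` — the model, conventions and design
  decisions in full
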