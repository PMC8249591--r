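#' Construct a response field
#'
#' A `response_field` holds a time x N_CF matrix of model outputs with a CF
#' axis and a units tag.  All teacher and surrogate stages produce and consume
#' response fields.
#'
#' @param values numeric matrix (time x N_CF) or vector (single channel).
#' @param fs sampling rate (Hz).
#' @param cf_axis strictly monotonic vector of characteristic frequencies (Hz).
#' @param units one of `"m"` (BM displacement), `"um_scaled"` (x1e6), `"V"`
#'   (receptor potential), `"dV_scaled"` (x10), `"spikes_per_s"`,
#'   `"x100_spikes_per_s"` (x1e-2), `"raw"`.
#' @export
response_field <- function(values, fs, cf_axis, units = "raw") {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  stopifnot(is.matrix(values), all(is.finite(values)), fs > 0,
            length(cf_axis) == ncol(values))
  if (length(cf_axis) > 1 && !all(diff(cf_axis) > 0) && !all(diff(cf_axis) < 0))
    stop("cf_axis must be strictly monotonic")
  units <- match.arg(units, c("m", "um_scaled", "V", "dV_scaled",
                              "spikes_per_s", "x100_spikes_per_s", "raw"))
  structure(list(values = values, fs = fs, cf_axis = as.numeric(cf_axis),
                 units = units),
            class = "response_field")
}

#' @export
print.response_field <- function(x, ...) {
  cat(sprintf("<response_field: %d samples x %d CFs @ %g Hz [%s]>\n",
              nrow(x$values), ncol(x$values), x$fs, x$units))
  invisible(x)
}

#' Default internal solver rate for the analytical models (Hz)
#' @export
SOLVE_FS <- 1e5

# ---------------------------------------------------------------------------
# Basilar-membrane stand-in
# ---------------------------------------------------------------------------

#' Parameters of the basilar-membrane stand-in
#'
#' A deliberately simple, fully documented desk-scale stand-in for cochlear
#' mechanics: a zero-phase, log-frequency Gaussian bandpass filter per CF with
#' an asymmetric shape (shallow low-frequency tail, steep high-frequency
#' flank), followed by memoryless broken-stick compression of displacement.
#' The shallow low-side tail plus compressive saturation reproduce the
#' level-dependent basal-ward spread of excitation qualitatively.
#'
#' The displacement scale is a stand-in unit, chosen (together with the
#' matching IHC Boltzmann constants) so that the x1e6 training scaling lands
#' the network inputs near unit variance; absolute displacements are not
#' meant to match physiological nanometre values.
#'
#' @param gain_m_per_pa linear mid-band gain (displacement units per Pa).
#' @param bw_low,bw_high Gaussian half-widths (octaves) below/above CF.
#' @param knee_m displacement at the compression knee (m).
#' @param comp_exp compressive exponent above the knee.
#' @export
bm_params <- function(gain_m_per_pa = 3e-4, bw_low = 1.2, bw_high = 0.35,
                      knee_m = 2.7e-7, comp_exp = 0.4) {
  list(gain_m_per_pa = gain_m_per_pa, bw_low = bw_low, bw_high = bw_high,
       knee_m = knee_m, comp_exp = comp_exp)
}

#' Basilar-membrane-like multichannel drive from an acoustic stimulus
#'
#' Filters the pressure waveform per CF (zero-phase FFT filtering with the
#' asymmetric log-Gaussian magnitude response of [bm_params()]) and applies
#' broken-stick compression.  Deterministic.
#'
#' @param stim a [stimulus()] (pressure, Pa).
#' @param cf_axis CFs in Hz.
#' @param params see [bm_params()].
#' @return a [response_field()] of BM-like displacement in m.
#' @export
bm_drive <- function(stim, cf_axis, params = bm_params()) {
  x <- stim$samples
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * stim$fs
  freqs[freqs > stim$fs / 2] <- stim$fs - freqs[freqs > stim$fs / 2]
  out <- matrix(0, n, length(cf_axis))
  for (j in seq_along(cf_axis)) {
    cf <- cf_axis[j]
    d <- log2(pmax(freqs, 1e-6) / cf)
    bw <- ifelse(d < 0, params$bw_low, params$bw_high)
    H <- exp(-0.5 * (d / bw)^2)
    H[1] <- 0
    v <- Re(stats::fft(X * H, inverse = TRUE)) / n * params$gain_m_per_pa
    out[, j] <- compress_displacement(v, params$knee_m, params$comp_exp)
  }
  response_field(out, stim$fs, cf_axis, "m")
}

compress_displacement <- function(v, knee, expo) {
  a <- abs(v)
  big <- a > knee
  v[big] <- sign(v[big]) * knee * (a[big] / knee)^expo
  v
}

# ---------------------------------------------------------------------------
# Inner-hair-cell transduction stand-in
# ---------------------------------------------------------------------------

#' Parameters of the IHC transduction stand-in
#'
#' Saturating (Boltzmann) mechano-electrical transduction followed by a
#' first-order membrane low-pass.  The Boltzmann operating point is offset
#' (`x0 > 0`) so depolarising displacements open more channels than
#' hyperpolarising ones close, producing the DC component of the receptor
#' potential.  The membrane cutoff (~650 Hz) makes the AC/DC ratio decline
#' with stimulus frequency above ~600-700 Hz.
#'
#' @param x0 Boltzmann offset (m).
#' @param s0 Boltzmann slope (m).
#' @param e_k potassium reversal potential (V).
#' @param e_t transduction reversal potential (V).
#' @param v_rest resting receptor potential (V); fixes the basal conductance.
#' @param cutoff_hz membrane low-pass cutoff (Hz).
#' @export
ihc_params <- function(x0 = 12e-7, s0 = 10e-7, e_k = -0.075, e_t = 0,
                       v_rest = -0.057, cutoff_hz = 650) {
  g0 <- 1 / (1 + exp(x0 / s0))                     # open fraction at rest
  # basal shunt B chosen so the resting balance lands exactly on v_rest
  B <- g0 * ((e_t - e_k) / (v_rest - e_k) - 1)
  list(x0 = x0, s0 = s0, e_k = e_k, e_t = e_t, v_rest = v_rest,
       cutoff_hz = cutoff_hz, g0 = g0, B = B)
}

#' Simulate the IHC transduction stand-in
#'
#' Per channel: `g(u) = 1/(1 + exp(-(u - x0)/s0))`, instantaneous target
#' potential `V_inf = e_k + (e_t - e_k) * g/(g + B)`, then a first-order
#' recursive low-pass with time constant `1/(2*pi*cutoff_hz)`.
#'
#' @param drive a [response_field()] of BM-like displacement (m), at the
#'   solver rate.
#' @param params see [ihc_params()].
#' @return a [response_field()] of receptor potential in V.
#' @export
simulate_ihc <- function(drive, params = ihc_params()) {
  stopifnot(inherits(drive, "response_field"))
  u <- drive$values
  g <- 1 / (1 + exp(-(u - params$x0) / params$s0))
  vinf <- params$e_k + (params$e_t - params$e_k) * g / (g + params$B)
  tau <- 1 / (2 * pi * params$cutoff_hz)
  a <- exp(-1 / (drive$fs * tau))
  out <- apply(vinf, 2, function(col) {
    as.numeric(stats::filter((1 - a) * col, a, method = "recursive",
                             init = params$v_rest))
  })
  if (is.vector(out)) out <- matrix(out, ncol = 1)
  response_field(out, drive$fs, drive$cf_axis, "V")
}

# ---------------------------------------------------------------------------
# Auditory-nerve-fiber synapse stand-in
# ---------------------------------------------------------------------------

#' Fiber parameter presets for the three-store synapse stand-in
#'
#' Presets for high-, medium- and low-spontaneous-rate fibers with target
#' spontaneous rates 68.5, 10 and 1 spikes/s and recovery-metric thresholds
#' 60, 65 and 75 dB SPL.  The rate gain `hgain` is solved analytically from
#' the silent steady state so that `hgain * c_ss` equals `sr_target` exactly.
#'
#' @param type `"hsr"`, `"msr"` or `"lsr"`.
#' @return a list of class `fiber_params` with stores/rates of the three-store
#'   stand-in (`y` replenishment, `M` factory size, `x` reprocessing return,
#'   `l` cleft loss, `r` reuptake, Boltzmann release `kmax`/`vhalf`/`sv`, rate
#'   gain `hgain`), plus `sr_target` and `threshold_dB`.
#' @export
fiber_preset <- function(type = c("hsr", "msr", "lsr")) {
  type <- match.arg(type)
  base <- list(M = 1, l = 2500, r = 6580, x = 66.3)
  p <- switch(type,
    hsr = c(base, list(y = 2.0, kmax = 15, vhalf = -0.0563, sv = 0.0005,
                       sr_target = 68.5, threshold_dB = 60)),
    msr = c(base, list(y = 1.5, kmax = 18, vhalf = -0.048, sv = 0.00225,
                       sr_target = 10, threshold_dB = 65)),
    lsr = c(base, list(y = 1.0, kmax = 20, vhalf = -0.045, sv = 0.0018,
                       sr_target = 1, threshold_dB = 75)))
  p$type <- type
  ss <- synapse_steady_state(p, v = ihc_params()$v_rest)
  p$hgain <- unname(p$sr_target / ss["c"])
  class(p) <- "fiber_params"
  p
}

# silent steady state of the three-store system at receptor potential v
synapse_steady_state <- function(p, v) {
  k0 <- p$kmax / (1 + exp(-(v - p$vhalf) / p$sv))
  c_ss <- p$y * p$M / (p$l + p$y * (p$l + p$r) / k0)
  q_ss <- c_ss * (p$l + p$r) / k0
  w_ss <- p$r * c_ss / p$x
  c(q = unname(q_ss), c = unname(c_ss), w = unname(w_ss), k0 = unname(k0))
}

#' Simulate the three-store ANF synapse stand-in
#'
#' Integrates the three-store diffusion system (free pool, cleft,
#' reprocessing) driven by a saturating function of the receptor potential,
#' with forward-Euler flux bookkeeping (see the compiled core).  Integration
#' starts from the silent steady state, so a silent input holds the output at
#' the preset spontaneous rate.
#'
#' @param vihc a [response_field()] of receptor potential (V) at the solver
#'   rate.
#' @param fiber a [fiber_preset()].
#' @param keep_states return store trajectories (for conservation checks).
#' @return a [response_field()] of instantaneous rate (spikes/s); when
#'   `keep_states` is TRUE, store trajectories and the budget residual are
#'   attached as attributes `states` and `budget_residual` (single channel
#'   only).
#' @export
simulate_anf <- function(vihc, fiber, keep_states = FALSE) {
  stopifnot(inherits(vihc, "response_field"), inherits(fiber, "fiber_params"))
  dt <- 1 / vihc$fs
  ss <- synapse_steady_state(fiber, v = ihc_params()$v_rest)
  ncf <- ncol(vihc$values)
  out <- matrix(0, nrow(vihc$values), ncf)
  extras <- NULL
  for (j in seq_len(ncf)) {
    res <- synapse_core(vihc$values[, j], dt,
                        fiber$y, fiber$M, fiber$x, fiber$l, fiber$r,
                        fiber$kmax, fiber$vhalf, fiber$sv, fiber$hgain,
                        ss["q"], ss["c"], ss["w"],
                        keep_states && ncf == 1)
    out[, j] <- res$rate
    if (keep_states && ncf == 1) extras <- res
  }
  rf <- response_field(out, vihc$fs, vihc$cf_axis, "spikes_per_s")
  if (!is.null(extras)) {
    attr(rf, "states") <- extras$states
    attr(rf, "budget_residual") <- extras$budget_residual
  }
  rf
}

#' Simulate the full teacher chain pressure -> BM -> IHC (-> ANF)
#'
#' Convenience wrapper running the analytical stand-ins in sequence at the
#' solver rate.
#'
#' @param stim a [stimulus()] at `SOLVE_FS`.
#' @param cf_axis CFs (Hz).
#' @param stage final stage: `"bm"`, `"ihc"` or `"anf"`.
#' @param fiber a [fiber_preset()] (required for `stage = "anf"`).
#' @export
simulate_periphery <- function(stim, cf_axis, stage = c("ihc", "bm", "anf"),
                               fiber = NULL) {
  stage <- match.arg(stage)
  bm <- bm_drive(stim, cf_axis)
  if (stage == "bm") return(bm)
  v <- simulate_ihc(bm)
  if (stage == "ihc") return(v)
  if (is.null(fiber)) stop("fiber preset required for the ANF stage")
  simulate_anf(v, fiber)
}

# ---------------------------------------------------------------------------
# Hodgkin-Huxley squid axon
# ---------------------------------------------------------------------------

#' Default Hodgkin-Huxley squid-axon parameters
#'
#' Classical coefficients: gNa = 120, gK = 36, gL = 0.3 mS/cm^2, ENa = 50,
#' EK = -77, EL = -54.387 mV, Cm = 1 uF/cm^2, rest near -65 mV.
#' @export
hh_params <- function() {
  list(gNa = 120, gK = 36, gL = 0.3, ENa = 50, EK = -77, EL = -54.387,
       Cm = 1, V0 = -65)
}

#' Simulate the standard Hodgkin-Huxley squid axon
#'
#' Four-state (V, m, h, n) integration with exponential-Euler gates and
#' forward-Euler voltage at the stimulus sampling rate (default solver rate
#' 100 kHz, i.e. dt = 0.01 ms).  Deterministic; aborts with a diagnostic on
#' non-finite state.
#'
#' @param current a [stimulus()] of kind `"step"` (uA/cm^2).
#' @param params see [hh_params()].
#' @param full return gating variables as well.
#' @return membrane potential waveform in mV (numeric vector), or a matrix
#'   `[V, m, h, n]` when `full = TRUE`.
#' @export
simulate_hh <- function(current, params = hh_params(), full = FALSE) {
  stopifnot(inherits(current, "stimulus"))
  dt_ms <- 1000 / current$fs
  out <- hh_core(current$samples, dt_ms, params$gNa, params$gK, params$gL,
                 params$ENa, params$EK, params$EL, params$Cm, params$V0)
  if (full) out else out[, 1]
}

#' Count action potentials by upward threshold crossing
#'
#' @param v membrane potential (mV).
#' @param threshold crossing level (mV), default 0.
#' @export
count_spikes <- function(v, threshold = 0) {
  above <- v > threshold
  sum(diff(above) == 1)
}

# ---------------------------------------------------------------------------
# Adaptation-time estimation and recovery metrics
# ---------------------------------------------------------------------------

#' Estimate the adaptation time of a response envelope
#'
#' The steady state is the mean of the final 10% of the (stimulated) response
#' segment.  The adaptation time is the first time after the envelope peak at
#' which the envelope enters, and remains within, +/-5% of the steady-state
#' value.  For oscillatory responses the envelope is the magnitude of the
#' analytic signal; rate-like responses are used raw.
#'
#' @param response numeric vector covering the stimulated segment.
#' @param fs sampling rate (Hz).
#' @param oscillatory use the analytic-signal (Hilbert) envelope.
#' @param band half-width of the tolerance band, as a fraction of the steady
#'   state (default 0.05).
#' @return adaptation time in seconds; 0 (with attribute `warn = TRUE`) when
#'   no peak rises above the steady state.
#' @export
estimate_adaptation_time <- function(response, fs, oscillatory = FALSE,
                                     band = 0.05) {
  env <- if (oscillatory) abs(analytic_signal(response)) else response
  n <- length(env)
  ss <- mean(env[max(1, floor(0.9 * n)):n])
  pk <- which.max(env)
  tol <- band * abs(ss)
  if (env[pk] <= ss + tol) {
    out <- 0
    attr(out, "warn") <- TRUE
    return(out)
  }
  inside <- abs(env - ss) <= tol
  # first index after the peak from which the envelope stays inside the band
  stay <- rev(cumprod(rev(inside))) > 0
  idx <- which(stay & seq_len(n) > pk)[1]
  if (is.na(idx)) return(structure((n - pk) / fs, warn = TRUE))
  (idx - pk) / fs
}

# analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Fraction of the steady-state response reached at a probe time
#'
#' Returns `rate(t_probe) / rate(t_ref)`, with both rates smoothed over a
#' 10-ms moving window.
#'
#' @param response numeric vector (rate over time, stimulus onset at t = 0).
#' @param fs sampling rate (Hz).
#' @param t_probe probe time (s), `< t_ref`.
#' @param t_ref reference time (s), `<=` response duration.
#' @param smooth_dur smoothing window (s), default 10 ms.
#' @export
steady_state_fraction <- function(response, fs, t_probe, t_ref,
                                  smooth_dur = 0.010) {
  stopifnot(t_probe < t_ref, t_ref <= length(response) / fs)
  w <- max(1, round(smooth_dur * fs))
  sm <- function(t) {
    i <- round(t * fs)
    idx <- max(1, i - w + 1):min(length(response), i)
    mean(response[idx])
  }
  ref <- sm(t_ref)
  if (ref == 0) stop("steady-state rate at t_ref is zero; fraction undefined")
  sm(t_probe) / ref
}

#' Onset-peak recovery curve of an ANF stand-in
#'
#' For each inter-stimulus interval, a pair of 100-ms tones at
#' `threshold + 40 dB` is run through the BM-IHC-ANF teacher chain at the
#' fiber's CF; the maximum rate during the second tone is normalised by the
#' maximum for the longest interval in the grid (1.9 s by convention, giving
#' a value of exactly 1 there).
#'
#' @param fiber a [fiber_preset()].
#' @param isi_grid intervals in seconds, within [0.1, 1.9].
#' @param freq probe tone frequency / CF (Hz), default 2 kHz.
#' @param fs solver rate.
#' @return a [metric_curve()] with x = isi (s), y = normalised onset peak.
#' @export
onset_recovery_curve <- function(fiber, isi_grid = seq(0.1, 1.9, by = 0.2),
                                 freq = 2000, fs = SOLVE_FS) {
  stopifnot(all(isi_grid >= 0.1 - 1e-9), all(isi_grid <= 1.9 + 1e-9))
  grid <- sort(unique(c(isi_grid, 1.9)))
  level <- fiber$threshold_dB + 40
  tone_dur <- 0.1
  peaks <- vapply(grid, function(isi) {
    stim <- tone_pair(freq, level, tone_dur, isi, fs)
    rate <- simulate_periphery(stim, freq, "anf", fiber)$values[, 1]
    i0 <- round((tone_dur + isi) * fs) + 1
    i1 <- min(length(rate), i0 + round(tone_dur * fs) - 1)
    max(rate[i0:i1])
  }, numeric(1))
  ref <- peaks[match(1.9, grid)]
  keep <- grid %in% isi_grid
  metric_curve(grid[keep], peaks[keep] / ref, x_units = "s",
               y_units = "normalised onset peak",
               meta = list(metric = "onset_recovery", freq = freq,
                           level_dB = level, fiber = fiber$type))
}
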