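#' Metric curve container
#'
#' @param x stimulus variable (level dB SPL, frequency Hz, CF Hz, time s or
#'   ISI s).
#' @param y metric values.
#' @param x_units,y_units unit tags.
#' @param meta list of stimulus parameters.
#' @export
metric_curve <- function(x, y, x_units = "", y_units = "", meta = list()) {
  stopifnot(length(x) == length(y))
  structure(list(x = as.numeric(x), y = as.numeric(y), x_units = x_units,
                 y_units = y_units, meta = meta),
            class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("<metric_curve (%s): %d points, x [%s], y [%s]>\n",
              if (is.null(x$meta$metric)) "?" else x$meta$metric,
              length(x$x), x$x_units, x$y_units))
  invisible(x)
}

#' Root-mean-square error
#'
#' `sqrt(mean((x - x_hat)^2))`; same units as the inputs.
#' @param x,x_hat equal-length numeric vectors.
#' @export
rmse <- function(x, x_hat) {
  if (length(x) != length(x_hat)) stop("shape mismatch in rmse")
  sqrt(mean((x - x_hat)^2))
}

#' Vector strength of a rate trace at the modulation frequency
#'
#' `|F(fm)| / |F(0)|` of the firing-rate trace: the magnitude of the
#' modulation-frequency Fourier component normalised by the DC component
#' (the mean rate).  Always in [0, 1] for non-negative rates.
#'
#' @param rate non-negative rate trace (spikes/s).
#' @param fs sampling rate (Hz).
#' @param fm modulation frequency (Hz); use an integer number of periods.
#' @export
vector_strength <- function(rate, fs, fm) {
  t <- (seq_along(rate) - 1) / fs
  num <- Mod(mean(rate * exp(-2i * pi * fm * t)))
  den <- mean(rate)
  if (den == 0) stop("zero mean rate: vector strength undefined")
  num / den
}

#' RMS of the half-wave rectified part of a response
#'
#' Zeroes negative samples and takes the RMS; for a pure sinusoid of
#' amplitude `a` this equals `a/2` in the continuous limit.
#' @param x numeric vector (already DC-subtracted).
#' @export
half_wave_rms <- function(x) sqrt(mean(pmax(x, 0)^2))

#' AC/DC ratio from a receptor-potential trace
#'
#' Convention: AC = RMS of the mean-subtracted steady-state segment (50-70 ms
#' after onset); DC = (steady-state mean) - (resting mean over 5-15 ms before
#' onset).  Returns NA when the DC component is zero.
#'
#' @param v receptor-potential trace (V).
#' @param fs sampling rate (Hz).
#' @param onset stimulus onset time (s).
#' @param ac_win,rest_win windows relative to onset (s).
#' @export
ac_dc_from_trace <- function(v, fs, onset, ac_win = c(0.050, 0.070),
                             rest_win = c(-0.015, -0.005)) {
  seg <- function(w) {
    i <- round((onset + w) * fs); v[max(1, i[1] + 1):min(length(v), i[2])]
  }
  steady <- seg(ac_win)
  rest <- seg(rest_win)
  ac <- sqrt(mean((steady - mean(steady))^2))
  dc <- mean(steady) - mean(rest)
  if (dc == 0) return(NA_real_)
  ac / dc
}

# ---------------------------------------------------------------------------
# Model wrappers: a common predict interface over teachers and surrogates
# ---------------------------------------------------------------------------

#' Wrap a model stage behind the metric interface
#'
#' A `periph_model` exposes `predict(stimulus) -> response_field` together
#' with its CF axis and input sampling rate, so the six metrics apply
#' identically to analytical teachers and trained surrogates.
#'
#' @param predict function of a [stimulus()] returning a [response_field()].
#' @param cf_axis CFs the model reports.
#' @param fs_in sampling rate stimuli should be generated at (Hz).
#' @param stage `"ihc"` or `"anf"`.
#' @param name label.
#' @export
periph_model <- function(predict, cf_axis, fs_in, stage, name = stage) {
  structure(list(predict = predict, cf_axis = cf_axis, fs_in = fs_in,
                 stage = stage, name = name),
            class = "periph_model")
}

#' Teacher stand-ins behind the metric interface
#'
#' @param stage `"ihc"` or `"anf"`.
#' @param cf_axis CFs to simulate.
#' @param fiber [fiber_preset()] for the `"anf"` stage.
#' @param fs solver rate.
#' @export
wrap_teacher_model <- function(stage = c("ihc", "anf"), cf_axis, fiber = NULL,
                               fs = SOLVE_FS) {
  stage <- match.arg(stage)
  periph_model(
    predict = function(stim) simulate_periphery(stim, cf_axis, stage, fiber),
    cf_axis = cf_axis, fs_in = fs, stage = stage,
    name = paste0("teacher_", stage))
}

#' Apply a trained surrogate to a full-length scaled sequence
#'
#' Feeds `[L_l zeros, x, right zero-pad]` (padding up to a multiple of the
#' total stride), runs the network, and crops back to the input length, so
#' the output is time-aligned with `x`.
#'
#' @param net a `surrogate_model`.
#' @param x vector or `time x n_cf` matrix in the net's scaled input units.
#' @export
surrogate_apply <- function(net, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  spec <- net$spec
  n <- nrow(x)
  div <- 2^(length(net$layers) / 2)
  total <- ceiling((spec$L_l + n + spec$L_r) / div) * div
  X <- rbind(matrix(0, spec$L_l, ncol(x)), x,
             matrix(0, total - spec$L_l - n, ncol(x)))
  y <- surrogate_predict(net, X)
  y[(spec$L_l + 1):(spec$L_l + n), , drop = FALSE]
}

#' Trained surrogate behind the metric interface
#'
#' Runs the analytical front end up to the surrogate's input stage at the
#' solver rate, resamples to the surrogate rate, applies the stage scaling,
#' the network, and the inverse scaling.
#'
#' @param net trained `surrogate_model`.
#' @param stage `"ihc"` (input: BM drive) or `"anf"` (input: receptor
#'   potential).
#' @param cf_axis CFs.
#' @param model_fs surrogate rate (Hz), default 20 kHz.
#' @param fs solver rate for the front end.
#' @export
wrap_surrogate_model <- function(net, stage = c("ihc", "anf"), cf_axis,
                                 model_fs = 2e4, fs = SOLVE_FS) {
  stage <- match.arg(stage)
  in_stage <- if (stage == "ihc") "bm" else "ihc"
  out_units <- if (stage == "ihc") "V" else "spikes_per_s"
  predict <- function(stim) {
    front <- simulate_periphery(stim, cf_axis,
                                if (in_stage == "bm") "bm" else "ihc")
    xr <- apply(front$values, 2, resample_to_model_rate, fs_in = fs,
                fs_out = model_fs)
    if (is.vector(xr)) xr <- matrix(xr, ncol = 1)
    xs <- scale_signal(xr, in_stage)
    y <- surrogate_apply(net, xs)
    response_field(unscale_signal(y, stage), model_fs, cf_axis, out_units)
  }
  periph_model(predict, cf_axis, fs, stage, name = paste0("surrogate_", stage))
}

# metric-specific stimulus defaults (ramps per paradigm; onset after leading
# silence long enough for the resting-window convention)
metric_defaults <- function() {
  list(onset = 0.020,
       m1 = list(ramp = 0.005, dur = 0.100),
       m2 = list(ramp = 0.005, dur = 0.080),
       m3 = list(ramp = 0.005, dur = 0.080),
       m4 = list(ramp_tone = 0.005, ramp_sam = 0.0078, dur = 0.400),
       m5 = list(ramp = 0.0025, dur = 0.050),
       m6 = list(ramp = 0.0078, dur = 0.400))
}

# a tone embedded after `onset` seconds of silence, padded to `total` seconds
embedded_tone <- function(freq, level_dB, dur, fs, ramp, onset, total) {
  tone <- pure_tone(freq, level_dB, dur, fs, ramp)$samples
  n <- round(total * fs)
  x <- numeric(n)
  i0 <- round(onset * fs) + 1
  x[i0:min(n, i0 + length(tone) - 1)] <- tone[seq_len(min(n - i0 + 1,
                                                          length(tone)))]
  stimulus(x, fs, level_dB, "tone")
}

embedded_sam <- function(freq, fm, m, level_dB, dur, fs, ramp, onset, total) {
  s <- sam_tone(freq, fm, m, level_dB, dur, fs, ramp)$samples
  n <- round(total * fs)
  x <- numeric(n)
  i0 <- round(onset * fs) + 1
  x[i0:min(n, i0 + length(s) - 1)] <- s[seq_len(min(n - i0 + 1, length(s)))]
  stimulus(x, fs, level_dB, "sam")
}

# ---------------------------------------------------------------------------
# Metric 1: excitation patterns
# ---------------------------------------------------------------------------

#' IHC excitation patterns across CF (Metric 1)
#'
#' Mean depolarisation (steady-state mean minus resting potential) of the
#' receptor potential at every CF, for pure tones of the given frequencies
#' and levels (5-ms ramps).
#'
#' @param model a `periph_model` (IHC stage).
#' @param freqs tone frequencies (Hz).
#' @param levels levels (dB SPL).
#' @return list of [metric_curve()] (x = CF), one per (freq, level).
#' @export
excitation_pattern <- function(model, freqs = c(500, 1000, 2000),
                               levels = seq(10, 90, by = 20)) {
  md <- metric_defaults()
  fs <- model$fs_in
  out <- list()
  for (f in freqs) for (L in levels) {
    stim <- embedded_tone(f, L, md$m1$dur, fs, md$m1$ramp, md$onset,
                          md$onset + md$m1$dur + 0.005)
    rf <- model$predict(stim)
    v <- rf$values
    o <- round(md$onset * rf$fs)
    steady <- (o + round(0.030 * rf$fs)):(o + round(0.095 * rf$fs))
    rest <- 1:round(0.015 * rf$fs)
    pat <- colMeans(v[steady, , drop = FALSE]) -
      colMeans(v[rest, , drop = FALSE])
    out[[sprintf("f%g_L%g", f, L)]] <-
      metric_curve(model$cf_axis, pat, "Hz (CF)", "V (mean depolarisation)",
                   meta = list(metric = "excitation_pattern", freq = f,
                               level_dB = L))
  }
  out
}

# ---------------------------------------------------------------------------
# Metric 2: AC/DC ratio
# ---------------------------------------------------------------------------

#' IHC AC/DC ratio across frequency (Metric 2)
#'
#' 80-ms tone bursts at 80 dB SPL presented at the probed CF; AC and DC
#' follow [ac_dc_from_trace()].
#'
#' @param model a `periph_model` (IHC stage).
#' @param freqs probe frequencies (Hz); each is matched to the nearest CF.
#' @param level level (dB SPL), default 80.
#' @export
ac_dc_ratio <- function(model, freqs = c(250, 500, 1000, 2000, 4000),
                        level = 80) {
  md <- metric_defaults()
  fs <- model$fs_in
  y <- vapply(freqs, function(f) {
    stim <- embedded_tone(f, level, md$m2$dur, fs, md$m2$ramp, md$onset,
                          md$onset + md$m2$dur + 0.010)
    rf <- model$predict(stim)
    j <- which.min(abs(model$cf_axis - f))
    ac_dc_from_trace(rf$values[, j], rf$fs, md$onset)
  }, numeric(1))
  metric_curve(freqs, y, "Hz", "AC/DC",
               meta = list(metric = "ac_dc_ratio", level_dB = level))
}

# ---------------------------------------------------------------------------
# Metric 3: potential-level growth
# ---------------------------------------------------------------------------

#' Half-wave-rectified receptor-potential growth with level (Metric 3)
#'
#' 4-kHz, 80-ms tones (5-ms ramps) from 0 to 100 dB SPL; the steady-state
#' response has its DC (steady-state mean) subtracted, negatives are zeroed
#' and the RMS is reported per level.
#'
#' @param model a `periph_model` (IHC stage).
#' @param freq probe frequency (Hz), default 4 kHz.
#' @param levels dB SPL.
#' @export
potential_level_growth <- function(model, freq = 4000,
                                   levels = seq(0, 100, by = 10)) {
  md <- metric_defaults()
  fs <- model$fs_in
  j <- which.min(abs(model$cf_axis - freq))
  y <- vapply(levels, function(L) {
    stim <- embedded_tone(freq, L, md$m3$dur, fs, md$m3$ramp, md$onset,
                          md$onset + md$m3$dur + 0.010)
    rf <- model$predict(stim)
    o <- round(md$onset * rf$fs)
    steady <- rf$values[(o + round(0.050 * rf$fs)):(o + round(0.070 * rf$fs)), j]
    half_wave_rms(steady - mean(steady))
  }, numeric(1))
  metric_curve(levels, y, "dB SPL", "V (half-wave rectified RMS)",
               meta = list(metric = "potential_level_growth", freq = freq))
}

# ---------------------------------------------------------------------------
# Metric 4: ANF firing rate over time
# ---------------------------------------------------------------------------

#' ANF firing rate versus time (Metric 4)
#'
#' Rate trace at the probed CF for 70-dB-SPL tone bursts (5-ms ramps) or SAM
#' tones (m = 1, fm = 100 Hz, 7.8-ms ramps).
#'
#' @param model a `periph_model` (ANF stage).
#' @param freq tone/carrier frequency (Hz).
#' @param kind `"tone"` or `"sam"`.
#' @param level dB SPL, default 70.
#' @export
firing_rate_response <- function(model, freq = 1000, kind = c("tone", "sam"),
                                 level = 70) {
  kind <- match.arg(kind)
  md <- metric_defaults()
  fs <- model$fs_in
  total <- md$onset + md$m4$dur + 0.020
  stim <- if (kind == "tone") {
    embedded_tone(freq, level, md$m4$dur, fs, md$m4$ramp_tone, md$onset, total)
  } else {
    embedded_sam(freq, 100, 1, level, md$m4$dur, fs, md$m4$ramp_sam, md$onset,
                 total)
  }
  rf <- model$predict(stim)
  j <- which.min(abs(model$cf_axis - freq))
  metric_curve((seq_len(nrow(rf$values)) - 1) / rf$fs, rf$values[, j],
               "s", "spikes/s",
               meta = list(metric = "firing_rate", freq = freq, kind = kind,
                           level_dB = level, onset = md$onset, fs = rf$fs))
}

# ---------------------------------------------------------------------------
# Metric 5: rate-level curves
# ---------------------------------------------------------------------------

#' ANF rate-level curve (Metric 5)
#'
#' 50-ms tones with 2.5-ms ramps at the probed CF; the mean rate 10-40 ms
#' after onset is reported per level.
#'
#' @param model a `periph_model` (ANF stage).
#' @param freq probe frequency (Hz); canonical probes are 1007 and 3972.7 Hz.
#' @param levels dB SPL.
#' @export
rate_level_curve <- function(model, freq = 1007,
                             levels = seq(0, 100, by = 10)) {
  md <- metric_defaults()
  fs <- model$fs_in
  j <- which.min(abs(model$cf_axis - freq))
  y <- vapply(levels, function(L) {
    stim <- embedded_tone(freq, L, md$m5$dur, fs, md$m5$ramp, md$onset,
                          md$onset + md$m5$dur + 0.020)
    rf <- model$predict(stim)
    o <- round(md$onset * rf$fs)
    mean(rf$values[(o + round(0.010 * rf$fs)):(o + round(0.040 * rf$fs)), j])
  }, numeric(1))
  metric_curve(levels, y, "dB SPL", "spikes/s",
               meta = list(metric = "rate_level", freq = freq))
}

# ---------------------------------------------------------------------------
# Metric 6: synchrony-level curves
# ---------------------------------------------------------------------------

#' ANF synchrony-level curve (Metric 6)
#'
#' 400-ms fully modulated (m = 1) SAM tones, fm = 100 Hz; the vector strength
#' of the rate trace at fm is reported per level.  The Fourier components are
#' taken over the steady-state portion (onset + 100 ms onwards, an integer
#' number of modulation periods).
#'
#' @param model a `periph_model` (ANF stage).
#' @param carrier carrier frequency (Hz); canonical probes 1007 / 3972.7 Hz.
#' @param fm modulation frequency (Hz), default 100.
#' @param levels dB SPL.
#' @export
synchrony_level_curve <- function(model, carrier = 1007, fm = 100,
                                  levels = seq(0, 100, by = 10)) {
  md <- metric_defaults()
  fs <- model$fs_in
  j <- which.min(abs(model$cf_axis - carrier))
  y <- vapply(levels, function(L) {
    stim <- embedded_sam(carrier, fm, 1, L, md$m6$dur, fs, md$m6$ramp,
                         md$onset, md$onset + md$m6$dur + 0.010)
    rf <- model$predict(stim)
    o <- round((md$onset + 0.100) * rf$fs)
    n_per <- floor((nrow(rf$values) - o) * fm / rf$fs)
    seg <- rf$values[(o + 1):(o + round(n_per * rf$fs / fm)), j]
    vector_strength(seg, rf$fs, fm)
  }, numeric(1))
  metric_curve(levels, y, "dB SPL", "vector strength",
               meta = list(metric = "synchrony_level", carrier = carrier,
                           fm = fm))
}

# ---------------------------------------------------------------------------
# Report
# ---------------------------------------------------------------------------

#' Evaluate a surrogate against its teacher on the metric suite
#'
#' Runs the selected metrics on both models and reports per-metric RMSE
#' between the curves.  `surrogate` and `teacher` are either `periph_model`s
#' of one stage, or named lists `list(ihc = , anf = )` so the full six-metric
#' suite can run in one report.
#'
#' @param surrogate,teacher `periph_model` or named list of them.
#' @param metric_suite metric names among `"excitation_pattern"`,
#'   `"ac_dc_ratio"`, `"potential_level_growth"`, `"firing_rate"`,
#'   `"rate_level"`, `"synchrony_level"`.
#' @param ... passed to the individual metric functions.
#' @return list with `metrics` (per metric: surrogate curve, teacher curve)
#'   and `rmse` (named numeric vector, units of each metric).
#' @export
evaluate_surrogate <- function(surrogate, teacher,
                               metric_suite = c("excitation_pattern",
                                                "ac_dc_ratio",
                                                "potential_level_growth",
                                                "firing_rate", "rate_level",
                                                "synchrony_level"), ...) {
  stage_of <- c(excitation_pattern = "ihc", ac_dc_ratio = "ihc",
                potential_level_growth = "ihc", firing_rate = "anf",
                rate_level = "anf", synchrony_level = "anf")
  pick <- function(m, stage) {
    if (inherits(m, "periph_model")) {
      if (m$stage != stage) stop("metric requires a ", stage, "-stage model")
      m
    } else m[[stage]]
  }
  fun_of <- list(excitation_pattern = excitation_pattern,
                 ac_dc_ratio = ac_dc_ratio,
                 potential_level_growth = potential_level_growth,
                 firing_rate = firing_rate_response,
                 rate_level = rate_level_curve,
                 synchrony_level = synchrony_level_curve)
  metrics <- list(); errs <- numeric(0)
  for (name in metric_suite) {
    st <- stage_of[[name]]
    cs <- fun_of[[name]](pick(surrogate, st), ...)
    ct <- fun_of[[name]](pick(teacher, st), ...)
    err <- if (name == "excitation_pattern") {
      rmse(unlist(lapply(cs, `[[`, "y")), unlist(lapply(ct, `[[`, "y")))
    } else rmse(cs$y, ct$y)
    metrics[[name]] <- list(surrogate = cs, teacher = ct)
    errs[name] <- err
  }
  list(metrics = metrics, rmse = errs)
}
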