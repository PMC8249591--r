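#' @useDynLib periphnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reference sound pressure (Pa)
#'
#' The reference pressure p0 = 2e-5 Pa defining 0 dB SPL.
#' @export
P0_PA <- 2e-5

#' Construct a stimulus object
#'
#' A `stimulus` is a calibrated single-channel waveform: sound pressure in Pa
#' for acoustic stimuli, or current density in uA/cm^2 for step currents.
#'
#' @param samples numeric vector of instantaneous amplitudes.
#' @param fs sampling rate in Hz (> 0).
#' @param level_dB nominal level in dB SPL, or `NULL` for current stimuli.
#' @param kind one of `"tone"`, `"sam"`, `"tone_pair"`, `"step"`,
#'   `"corpus_item"`.
#' @return an object of class `stimulus`.
#' @export
stimulus <- function(samples, fs, level_dB = NULL, kind = "tone") {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs > 0)
  kind <- match.arg(kind, c("tone", "sam", "tone_pair", "step", "corpus_item"))
  structure(list(samples = as.numeric(samples), fs = fs,
                 level_dB = level_dB, kind = kind),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus: %s, %d samples @ %g Hz, level %s>\n",
              x$kind, length(x$samples), x$fs,
              if (is.null(x$level_dB)) "NA" else sprintf("%g dB SPL", x$level_dB)))
  invisible(x)
}

#' RMS level of a waveform in dB SPL
#'
#' @param x numeric vector or `stimulus`.
#' @return 20*log10(RMS / p0) with p0 = 2e-5 Pa.
#' @export
rms_level_dB <- function(x) {
  if (inherits(x, "stimulus")) x <- x$samples
  20 * log10(sqrt(mean(x^2)) / P0_PA)
}

# rising half of a raised-cosine (Hann) window, length n, from 0 to 1
hann_ramp <- function(n) {
  if (n <= 1) return(rep(1, max(n, 0)))
  0.5 * (1 - cos(pi * (seq_len(n) - 1) / (n - 1)))
}

#' Apply raised-cosine onset/offset ramps in place
#'
#' Each ramp is the first (respectively last) half of a raised-cosine window of
#' length `2 * ramp_dur`.  Ramping is multiplicative and never re-normalises,
#' so a ramped waveform always has lower RMS than its unramped original.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param ramp_dur ramp duration in seconds (each side); 0 disables ramping.
#' @export
apply_ramp <- function(x, fs, ramp_dur) {
  if (ramp_dur <= 0) return(x)
  n <- round(ramp_dur * fs)
  if (n < 1) return(x)
  stopifnot(length(x) >= 2 * n)
  w <- hann_ramp(n)
  x[seq_len(n)] <- x[seq_len(n)] * w
  x[(length(x) - n + 1):length(x)] <- x[(length(x) - n + 1):length(x)] * rev(w)
  x
}

#' Calibrated pure tone
#'
#' Generates `p0 * sqrt(2) * 10^(L/20) * sin(2*pi*f*t)`, so that the unramped
#' RMS equals the requested level exactly; raised-cosine ramps are applied
#' multiplicatively after calibration (no re-normalisation).
#'
#' @param freq tone frequency (Hz), must be below fs/2.
#' @param level_dB RMS level in dB SPL.
#' @param duration duration in seconds; must exceed `2 * ramp_dur`.
#' @param fs sampling rate (Hz).
#' @param ramp_dur per-side ramp duration in seconds (default 5 ms).
#' @return a `stimulus` of kind `"tone"`.
#' @export
pure_tone <- function(freq, level_dB, duration, fs, ramp_dur = 0.005) {
  if (freq >= fs / 2) stop("aliasing: tone frequency ", freq,
                           " Hz is not below fs/2 = ", fs / 2, " Hz")
  if (duration <= 0) stop("duration must be positive")
  if (ramp_dur < 0 || duration <= 2 * ramp_dur)
    stop("duration must exceed twice the ramp duration")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- P0_PA * sqrt(2) * 10^(level_dB / 20)
  x <- amp * sin(2 * pi * freq * t)
  x <- apply_ramp(x, fs, ramp_dur)
  stimulus(x, fs, level_dB, "tone")
}

#' Sinusoidally amplitude-modulated (SAM) tone
#'
#' Waveform `[1 + m*cos(2*pi*fm*t + pi)] * sin(2*pi*fc*t)`: the pi phase
#' offset places an envelope zero at onset for m = 1.  The whole waveform is
#' rescaled after envelope construction so its full-duration RMS matches the
#' requested level, then ramped (7.8 ms per side by default).
#'
#' @param carrier carrier frequency (Hz), below fs/2.
#' @param fm modulation frequency (Hz).
#' @param m modulation depth in [0, 1].
#' @param level_dB RMS level in dB SPL (of the full ramp-free waveform).
#' @param duration seconds.
#' @param fs sampling rate (Hz).
#' @param ramp_dur per-side ramp (s), default 7.8 ms.
#' @return a `stimulus` of kind `"sam"`.
#' @export
sam_tone <- function(carrier, fm, m, level_dB, duration, fs,
                     ramp_dur = 0.0078) {
  if (m < 0 || m > 1) stop("modulation depth m must lie in [0, 1]")
  if (carrier >= fs / 2) stop("aliasing: carrier ", carrier,
                              " Hz is not below fs/2 = ", fs / 2, " Hz")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- (1 + m * cos(2 * pi * fm * t + pi)) * sin(2 * pi * carrier * t)
  target_rms <- P0_PA * 10^(level_dB / 20)
  x <- x * target_rms / sqrt(mean(x^2))
  x <- apply_ramp(x, fs, ramp_dur)
  stimulus(x, fs, level_dB, "sam")
}

#' Pair of identical tones separated by silence
#'
#' Two identical ramped pure tones with an inter-stimulus interval of exact
#' zeros, used to probe onset-peak recovery.  Fiber-threshold presets place
#' the tones 40 dB above threshold: 60/65/75 dB SPL thresholds for the
#' high-/medium-/low-spontaneous-rate fibers.
#'
#' @param freq tone frequency (Hz).
#' @param level_dB level of each tone (dB SPL).
#' @param tone_dur duration of each tone (s), default 100 ms.
#' @param isi inter-stimulus interval (s), >= 0.
#' @param fs sampling rate (Hz).
#' @param ramp_dur per-side ramp (s).
#' @return a `stimulus` of kind `"tone_pair"`.
#' @export
tone_pair <- function(freq, level_dB, tone_dur = 0.1, isi, fs,
                      ramp_dur = 0.005) {
  if (isi < 0) stop("isi must be >= 0")
  tone <- pure_tone(freq, level_dB, tone_dur, fs, ramp_dur)$samples
  gap <- rep(0, round(isi * fs))
  stimulus(c(tone, gap, tone), fs, level_dB, "tone_pair")
}

#' Step current stimulus
#'
#' Zero before onset, constant amplitude (uA/cm^2) for `dur` seconds, zero
#' afterwards.  Used to drive the Hodgkin-Huxley axon model.
#'
#' @param amplitude current density (uA/cm^2), >= 0.
#' @param onset onset time (s).
#' @param dur pulse duration (s).
#' @param fs sampling rate (Hz).
#' @param total total stimulus duration (s); default `onset + dur + onset`.
#' @return a `stimulus` of kind `"step"` (level_dB is NULL).
#' @export
step_current <- function(amplitude, onset, dur, fs, total = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (is.null(total)) total <- onset + dur + onset
  n <- round(total * fs)
  x <- rep(0, n)
  i0 <- round(onset * fs) + 1
  i1 <- i0 + round(dur * fs) - 1
  x[i0:min(i1, n)] <- amplitude
  stimulus(x, fs, NULL, "step")
}

#' Batch of step currents with random amplitudes
#'
#' Amplitudes drawn uniformly from `[0, 1000]` uA/cm^2 under a fixed seed
#' (reproducible bitwise).
#'
#' @param n_items number of stimuli.
#' @param onset,dur,fs,total as in [step_current()].
#' @param seed integer RNG seed.
#' @export
step_current_batch <- function(n_items, onset, dur, fs, total = NULL,
                               seed = 1L) {
  amps <- with_local_seed(seed, stats::runif(n_items, 0, 1000))
  lapply(amps, step_current, onset = onset, dur = dur, fs = fs, total = total)
}

# run expr under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Seeded synthetic speech-like corpus
#'
#' A stand-in for a recorded speech corpus: pink-weighted noise in 8
#' logarithmically spaced bands (100 Hz - 0.4*fs), each multiplied by an
#' independent slow (2-10 Hz) envelope, summed, and RMS-calibrated.  Half the
#' items are set to 70 dB SPL and half to 130 dB SPL so the set spans the
#' dynamic range needed to learn saturation properties; for odd `n_items` the
#' first `ceiling(n/2)` items take 70 dB.
#'
#' @param n_items number of items (>= 2).
#' @param dur item duration (s).
#' @param fs sampling rate (Hz).
#' @param seed integer seed; the corpus is bitwise-reproducible.
#' @param levels_dB the two calibration levels, default `c(70, 130)`.
#' @return list of `stimulus` objects of kind `"corpus_item"`.
#' @export
speech_like_corpus <- function(n_items, dur, fs, seed = 1L,
                               levels_dB = c(70, 130)) {
  if (n_items < 2) stop("n_items must be >= 2")
  n <- round(dur * fs)
  n70 <- ceiling(n_items / 2)
  with_local_seed(seed, {
    lapply(seq_len(n_items), function(i) {
      x <- speech_like_item(n, fs)
      lev <- if (i <= n70) levels_dB[1] else levels_dB[2]
      x <- x * (P0_PA * 10^(lev / 20)) / sqrt(mean(x^2))
      stimulus(x, fs, lev, "corpus_item")
    })
  })
}

# one pink-weighted, envelope-modulated band-noise item (uncalibrated)
speech_like_item <- function(n, fs, n_bands = 8) {
  edges <- exp(seq(log(100), log(0.4 * fs), length.out = n_bands + 1))
  t <- (seq_len(n) - 1) / fs
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  out <- numeric(n)
  for (b in seq_len(n_bands)) {
    z <- stats::rnorm(n)
    Z <- stats::fft(z)
    keep <- freqs >= edges[b] & freqs < edges[b + 1]
    full <- band_mask_full(n, keep, length(freqs))
    band <- Re(stats::fft(Z * full, inverse = TRUE)) / n
    # pink weighting ~ 1/sqrt(f_centre)
    fc <- sqrt(edges[b] * edges[b + 1])
    band <- band / sqrt(fc)
    # slow envelope, 2-10 Hz raised sinusoid with random rate and phase
    fr <- stats::runif(1, 2, 10)
    ph <- stats::runif(1, 0, 2 * pi)
    env <- 0.55 + 0.45 * sin(2 * pi * fr * t + ph)
    out <- out + band * env
  }
  out
}

# full-length symmetric FFT mask from a half-spectrum keep vector
band_mask_full <- function(n, keep, nh) {
  full <- numeric(n)
  full[seq_len(nh)] <- as.numeric(keep)
  if (n > nh) {
    # mirror bins 2..(n - nh + 1) onto the negative-frequency half
    idx <- 2:(n - nh + 1)
    full[n:(nh + 1)] <- full[idx]
  }
  full
}

#' RMS level within short time bins
#'
#' Splits a waveform into consecutive bins (default 4 ms) and returns the RMS
#' level of each bin in dB SPL (empty/zero bins give -Inf).
#'
#' @param x `stimulus` or numeric vector.
#' @param fs sampling rate (required when `x` is a bare vector).
#' @param bin_dur bin duration (s), default 4 ms.
#' @export
binned_levels_dB <- function(x, fs = NULL, bin_dur = 0.004) {
  if (inherits(x, "stimulus")) { fs <- x$fs; x <- x$samples }
  nb <- round(bin_dur * fs)
  nfull <- floor(length(x) / nb)
  m <- matrix(x[seq_len(nfull * nb)], nrow = nb)
  20 * log10(sqrt(colMeans(m^2)) / P0_PA)
}
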