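#' Anti-aliased rational-rate resampling
#'
#' Polyphase resampling from `fs_in` to `fs_out` (rational ratio required):
#' zero-stuff upsampling by `p`, a zero-phase Kaiser-windowed FIR low-pass at
#' 0.95x the narrower Nyquist (stopband ~80 dB; the linear-phase delay is
#' compensated exactly), then decimation by `q`.  Output length is
#' `round(len * fs_out / fs_in)`.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out sampling rates (Hz).
#' @return resampled vector.
#' @export
resample_to_model_rate <- function(x, fs_in = 1e5, fs_out = 2e4) {
  if (fs_in == fs_out) return(x)
  fr <- ratio_pq(fs_out / fs_in)
  p <- fr[1]; q <- fr[2]
  n_in <- length(x)
  if (p > 1) {
    up <- numeric(n_in * p)
    up[seq(1, length(up), by = p)] <- x * p
    x <- up
  }
  fs_up <- fs_in * p
  cutoff <- 0.95 * min(fs_in, fs_out) / 2
  ntaps <- 4 * ceiling(fs_up / cutoff) * 16 + 1
  ntaps <- min(ntaps, 2001)
  h <- signal::fir1(ntaps - 1, cutoff / (fs_up / 2),
                    window = signal::kaiser(ntaps, 7.85))
  hw <- (ntaps - 1) / 2
  y <- signal::fftfilt(h, c(x, numeric(ntaps)))   # causal; delay hw samples
  y <- as.numeric(y)[(hw + 1):(hw + length(x))]   # delay-compensated: zero phase
  y <- y[seq(1, length(y), by = q)]
  n_out <- round(n_in * fs_out / fs_in)
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

# small-denominator rational approximation of a rate ratio
ratio_pq <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("sampling-rate ratio is not rational within denominator ", max_den)
}

#' Stage-specific unit scaling
#'
#' Scales simulated responses into training units: BM displacement x1e6
#' ([m] -> [um]), IHC receptor potential x10 ([V] -> [dV]), ANF rate x1e-2
#' ([spikes/s] -> [x100 spikes/s]).  These factors keep the training data
#' near unit scale.  `unscale_signal()` is the exact inverse.
#'
#' @param x numeric vector/matrix or [response_field()].
#' @param stage `"bm"`, `"ihc"` or `"anf"`.
#' @export
scale_signal <- function(x, stage) {
  f <- stage_scale_factor(stage)
  if (inherits(x, "response_field")) {
    units <- switch(stage, bm = "um_scaled", ihc = "dV_scaled",
                    anf = "x100_spikes_per_s")
    return(response_field(x$values * f, x$fs, x$cf_axis, units))
  }
  x * f
}

#' @rdname scale_signal
#' @export
unscale_signal <- function(x, stage) {
  f <- stage_scale_factor(stage)
  if (inherits(x, "response_field")) {
    units <- switch(stage, bm = "m", ihc = "V", anf = "spikes_per_s")
    return(response_field(x$values / f, x$fs, x$cf_axis, units))
  }
  x / f
}

stage_scale_factor <- function(stage) {
  switch(match.arg(stage, c("bm", "ihc", "anf")),
         bm = 1e6, ihc = 10, anf = 1e-2)
}

#' Pad a waveform with leading and trailing silence
#'
#' Exact zeros: 0.5 s before and 1 s after by default (the convention used
#' for synapse-stage training so recovery/adaptation from silence is in the
#' data).
#'
#' @param x numeric vector or matrix (time in rows).
#' @param fs sampling rate (Hz).
#' @param pre,post durations (s).
#' @export
add_silence <- function(x, fs, pre = 0.5, post = 1.0) {
  if (is.vector(x)) {
    c(numeric(round(pre * fs)), x, numeric(round(post * fs)))
  } else {
    rbind(matrix(0, round(pre * fs), ncol(x)), x,
          matrix(0, round(post * fs), ncol(x)))
  }
}

#' Slice a sequence into overlapping context-padded windows
#'
#' Target windows of length `L` with hop `L * (1 - overlap)`; each input
#' window carries `L_l` preceding and `L_r` following context samples,
#' zero-filled beyond the signal edges.  The window count is
#' `floor((len - L)/hop) + 1`; an input shorter than `L` yields a single
#' zero-padded window with a warning.
#'
#' @param x numeric vector.
#' @param L target window length (samples).
#' @param overlap fractional overlap (default 0.5).
#' @param L_l,L_r context lengths (samples).
#' @return list with `inputs` (n x L_c matrix), `targets_idx` (n x 2 start/end
#'   sample indices of each target window in `x`).
#' @export
slice_windows <- function(x, L, overlap = 0.5, L_l = 0, L_r = 0) {
  len <- length(x)
  hop <- round(L * (1 - overlap))
  stopifnot(hop >= 1)
  if (len < L) {
    warning("input shorter than one window; zero-padding a single window")
    x <- c(x, numeric(L - len))
    len <- L
  }
  n <- floor((len - L) / hop) + 1
  L_c <- L_l + L + L_r
  inputs <- matrix(0, n, L_c)
  targets <- matrix(0L, n, 2)
  xp <- c(numeric(L_l), x, numeric(L_r))
  for (i in seq_len(n)) {
    s <- (i - 1) * hop + 1
    inputs[i, ] <- xp[s:(s + L_c - 1)]
    targets[i, ] <- c(s, s + L - 1)
  }
  list(inputs = inputs, targets_idx = targets, L = L, L_l = L_l, L_r = L_r,
       hop = hop)
}

#' Flatten CF channels of paired response fields into 1-D training sequences
#'
#' Each CF channel of each (input, target) response-field pair becomes an
#' independent single-channel sequence (the surrogate is CF-agnostic):
#' `n_items` items x `N_CF` channels give `n_items * N_CF` sequences.
#'
#' @param field_pairs list of `list(input = response_field, target =
#'   response_field)` sharing shape and cf_axis.
#' @return list of `list(input = vector, target = vector, cf = numeric)`.
#' @export
flatten_cf <- function(field_pairs) {
  n_cf <- vapply(field_pairs, function(p) length(p$input$cf_axis), numeric(1))
  out <- vector("list", sum(n_cf))
  pos <- 0L
  for (p in field_pairs) {
    a <- p$input; b <- p$target
    if (!identical(dim(a$values), dim(b$values)) ||
        !isTRUE(all.equal(a$cf_axis, b$cf_axis)))
      stop("paired response fields must share shape and cf_axis")
    for (j in seq_along(a$cf_axis)) {
      pos <- pos + 1L
      out[[pos]] <- list(input = a$values[, j], target = b$values[, j],
                         cf = a$cf_axis[j])
    }
  }
  out
}

#' Greenwood place-frequency CF axis
#'
#' CFs uniformly spaced in the Greenwood place coordinate of the human
#' cochlea, `f(x) = A * (10^(a*x) - k)` with A = 165.4 Hz, a = 2.1, k = 0.88,
#' with the endpoint places solved so the first and last CF equal
#' `f_min`/`f_max` exactly.
#'
#' @param n_cf number of CFs (>= 2), default 201.
#' @param f_min,f_max endpoint CFs (Hz), defaults 112 Hz and 12 kHz.
#' @export
greenwood_cf_axis <- function(n_cf = 201, f_min = 112, f_max = 12000) {
  stopifnot(n_cf >= 2)
  if (f_min >= f_max) stop("f_min must be below f_max")
  A <- 165.4; a <- 2.1; k <- 0.88
  place <- function(f) log10(f / A + k) / a
  x <- seq(place(f_min), place(f_max), length.out = n_cf)
  A * (10^(a * x) - k)
}

#' Training-window set
#'
#' Paired, scaled, context-padded input/target windows plus provenance.
#' @param inputs n x L_c matrix (scaled units).
#' @param targets n x L matrix (scaled units).
#' @param scaling list of stage tags for input/target.
#' @param provenance list (seed, corpus description, stage).
#' @param spec the [surrogate_spec()] whose geometry the windows match.
#' @export
training_window_set <- function(inputs, targets, scaling, provenance, spec) {
  stopifnot(nrow(inputs) == nrow(targets),
            ncol(inputs) == spec$L_c, ncol(targets) == spec$L,
            all(is.finite(inputs)), all(is.finite(targets)))
  structure(list(inputs = inputs, targets = targets, scaling = scaling,
                 provenance = provenance, spec = spec),
            class = "training_window_set")
}

#' @export
print.training_window_set <- function(x, ...) {
  cat(sprintf("<training_window_set: %d windows of %d -> %d samples [%s -> %s]>\n",
              nrow(x$inputs), ncol(x$inputs), ncol(x$targets),
              x$scaling$input, x$scaling$target))
  invisible(x)
}

#' Build a training set by running the teacher chain over a corpus
#'
#' Full data pipeline: simulate the analytical stand-ins at the solver rate,
#' resample to the model rate (20 kHz), apply stage scalings, add
#' leading/trailing silence (synapse stage only), slice into 50%-overlap
#' context windows, and flatten CF channels into independent sequences.
#' Deterministic for a fixed corpus.
#'
#' @param corpus list of [stimulus()] at the solver rate.
#' @param stage `"ihc"` (BM drive -> receptor potential) or `"anf"`
#'   (receptor potential -> firing rate).
#' @param spec the target [surrogate_spec()].
#' @param cf_axis CFs to simulate.
#' @param fiber [fiber_preset()] for the `"anf"` stage.
#' @param model_fs surrogate sampling rate (Hz), default 20 kHz.
#' @param seed provenance seed recorded in the set.
#' @param max_windows optional cap (deterministic head) on the window count.
#' @return a [training_window_set()].
#' @export
build_training_set <- function(corpus, stage = c("ihc", "anf"), spec, cf_axis,
                               fiber = NULL, model_fs = 2e4, seed = NA,
                               max_windows = Inf) {
  stage <- match.arg(stage)
  in_stage <- if (stage == "ihc") "bm" else "ihc"
  pairs <- lapply(corpus, function(stim) {
    if (stage == "anf") {
      # silence is added to the acoustic waveform, so the simulated responses
      # carry true resting/spontaneous segments and recovery from silence
      stim <- stimulus(add_silence(stim$samples, stim$fs), stim$fs,
                       stim$level_dB, stim$kind)
    }
    bm <- bm_drive(stim, cf_axis)
    if (stage == "ihc") {
      list(input = bm, target = simulate_ihc(bm))
    } else {
      v <- simulate_ihc(bm)
      list(input = v, target = simulate_anf(v, fiber))
    }
  })
  seqs <- flatten_cf(pairs)
  ins <- NULL; tgt <- NULL
  for (s in seqs) {
    xi <- resample_to_model_rate(s$input, corpus[[1]]$fs, model_fs)
    xt <- resample_to_model_rate(s$target, corpus[[1]]$fs, model_fs)
    xi <- scale_signal(xi, in_stage)
    xt <- scale_signal(xt, stage)
    sw_i <- slice_windows(xi, spec$L, 0.5, spec$L_l, spec$L_r)
    sw_t <- slice_windows(xt, spec$L, 0.5, 0, 0)
    ins <- rbind(ins, sw_i$inputs)
    tgt <- rbind(tgt, sw_t$inputs)
    if (nrow(ins) >= max_windows) break
  }
  if (nrow(ins) > max_windows) {
    ins <- ins[seq_len(max_windows), , drop = FALSE]
    tgt <- tgt[seq_len(max_windows), , drop = FALSE]
  }
  training_window_set(ins, tgt,
                      scaling = list(input = in_stage, target = stage),
                      provenance = list(seed = seed, stage = stage,
                                        n_items = length(corpus),
                                        n_cf = length(cf_axis)),
                      spec = spec)
}

#' Save / load a training-window set
#'
#' Native-R serialisation plus a JSON manifest with geometry, scaling and
#' provenance.
#' @param ws a [training_window_set()].
#' @param path file path.
#' @export
save_window_set <- function(ws, path) {
  saveRDS(ws, path)
  jsonlite::write_json(
    list(n_windows = nrow(ws$inputs), L_c = ncol(ws$inputs),
         L = ncol(ws$targets), scaling = ws$scaling,
         provenance = ws$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_window_set
#' @export
load_window_set <- function(path) {
  ws <- readRDS(path)
  stopifnot(inherits(ws, "training_window_set"))
  ws
}
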