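#' Receptive field of a strided convolutional encoder
#'
#' For `N` stacked convolution layers with filter length `k` and stride `s`,
#' the receptive field of one unit of the deepest layer is
#' `r_N = sum_{n=1..N} (k - 1) * s^(n-1) + 1`; for stride 2 this equals
#' `(k - 1) * (2^N - 1) + 1`.
#'
#' @param n_layers number of encoder layers N (>= 1).
#' @param kernel filter length k (>= 1), in samples.
#' @param stride stride s (>= 1), default 2.
#' @return receptive-field size in samples.
#' @export
receptive_field <- function(n_layers, kernel, stride = 2) {
  stopifnot(n_layers >= 1, kernel >= 1, stride >= 1)
  sum((kernel - 1) * stride^(seq_len(n_layers) - 1)) + 1
}

#' Minimal encoder depth whose receptive field exceeds a target
#'
#' Smallest `N` with `receptive_field(N, k, s) > target_rf` (strict
#' inequality: the receptive field must be larger than the input window).
#'
#' @param target_rf target length in samples (>= 1).
#' @param kernel filter length (>= 2 for termination when stride = 1).
#' @param stride stride, default 2.
#' @export
min_encoder_layers <- function(target_rf, kernel, stride = 2) {
  stopifnot(target_rf >= 1, kernel >= 2)
  n <- 1
  while (receptive_field(n, kernel, stride) <= target_rf) n <- n + 1
  n
}

#' Architecture advice from an adaptation time
#'
#' Converts the adaptation time course of an analytical model into candidate
#' encoder depths: the target receptive field is `ceil(adaptation_time * fs)`
#' samples, and for each candidate filter length the minimal stride-2 depth is
#' returned, together with a recommended training window `L` (the smallest
#' multiple of `2^N` that is >= the target, so the window is divisible by the
#' total stride).
#'
#' @param adaptation_time seconds (>= 0).
#' @param fs model sampling rate (Hz).
#' @param kernel_options candidate filter lengths.
#' @return data.frame with columns `kernel`, `n_layers`, `rf`, `rf_ms`, `L`.
#' @export
advise_architecture <- function(adaptation_time, fs,
                                kernel_options = c(8, 16, 32, 64, 128)) {
  stopifnot(adaptation_time >= 0, fs > 0)
  target <- max(1, ceiling(adaptation_time * fs))
  rows <- lapply(kernel_options, function(k) {
    n <- min_encoder_layers(target, k, 2)
    rf <- receptive_field(n, k, 2)
    L <- 2^n * ceiling(target / 2^n)
    data.frame(kernel = k, n_layers = n, rf = rf, rf_ms = 1000 * rf / fs,
               L = L)
  })
  out <- do.call(rbind, rows)
  attr(out, "target_rf") <- target
  out
}

#' Gradient-support receptive field of a built encoder (oracle)
#'
#' Brute-force check of the closed-form receptive field: builds the encoder of
#' a surrogate with random weights, backpropagates a unit gradient from one
#' centred bottleneck unit, and counts the input samples with non-zero
#' gradient.  Independent of [receptive_field()] (it exercises the actual
#' convolution code path).
#'
#' @param n_layers encoder depth (kept small; cost grows as 2^N).
#' @param kernel filter length.
#' @param filters filters per layer.
#' @param seed weight-initialisation seed.
#' @return number of input samples influencing the probed unit.
#' @export
gradient_support_rf <- function(n_layers, kernel, filters = 4, seed = 1L) {
  rf <- receptive_field(n_layers, kernel, 2)
  # input long enough that the probed (centred) unit sees no boundary
  L_in <- 2^n_layers * ceiling(4 * rf / 2^n_layers)
  spec <- surrogate_spec(L = L_in, L_l = 0, L_r = 0,
                         n_total = 2 * n_layers, filters = filters,
                         kernel = kernel, enc_act = "tanh", dec_act = "tanh")
  net <- build_surrogate(spec, seed = seed)
  x <- matrix(0, L_in, 1)
  enc <- net$layers[seq_len(n_layers)]
  fw <- network_forward_layers(enc, x, n_windows = 1L)
  bott <- fw$out
  dB <- matrix(0, nrow(bott), ncol(bott))
  dB[ceiling(nrow(bott) / 2), 1] <- 1
  dx <- network_backward_layers(enc, fw$caches, dB, n_windows = 1L)$dx
  sum(abs(dx[, 1]) > 0)
}
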