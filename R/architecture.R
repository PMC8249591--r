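#' Surrogate architecture specification
#'
#' Full description of an encoder-decoder surrogate: output window `L`,
#' left/right context `L_l`/`L_r` (input window `L_c = L_l + L + L_r`), an
#' even total number of convolution layers (`n_total/2` strided encoder
#' convolutions, `n_total/2` transposed decoder convolutions, stride 2
#' throughout), filters per layer, filter length, and the encoder/decoder
#' activations.  `L_c` must be divisible by `2^(n_total/2)` so the bottleneck
#' length is integral; the final decoder layer has no activation.
#'
#' @param L output window (samples).
#' @param L_l,L_r left/right context (samples).
#' @param n_total total number of convolutional layers (even, >= 4).
#' @param filters filters per layer.
#' @param kernel filter length (samples, >= 2).
#' @param enc_act,dec_act `"tanh"`, `"sigmoid"` or `"prelu"`.
#' @param out_channels output channels (1).
#' @return object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(L, L_l, L_r, n_total, filters, kernel,
                           enc_act = "tanh", dec_act = "sigmoid",
                           out_channels = 1) {
  stopifnot(L >= 1, L_l >= 0, L_r >= 0, kernel >= 2, filters >= 1,
            n_total %% 2 == 0, n_total >= 2, out_channels == 1)
  enc_act <- match.arg(enc_act, c("tanh", "sigmoid", "prelu"))
  dec_act <- match.arg(dec_act, c("tanh", "sigmoid", "prelu"))
  L_c <- L_l + L + L_r
  n_enc <- n_total / 2
  if (L_c %% 2^n_enc != 0)
    stop("input window L_c = ", L_c, " must be a multiple of 2^",
         n_enc, " = ", 2^n_enc)
  structure(list(L = L, L_l = L_l, L_r = L_r, L_c = L_c, n_total = n_total,
                 filters = filters, kernel = kernel, enc_act = enc_act,
                 dec_act = dec_act, out_channels = out_channels),
            class = "surrogate_spec")
}

#' @export
print.surrogate_spec <- function(x, ...) {
  cat(sprintf(paste0("<surrogate_spec: L=%d (ctx %d+%d, L_c=%d), %d layers,",
                     " %d filters, kernel %d, %s/%s>\n"),
              x$L, x$L_l, x$L_r, x$L_c, x$n_total, x$filters, x$kernel,
              x$enc_act, x$dec_act)
  )
  invisible(x)
}

#' Reference preset architectures
#'
#' The four final architectures: the IHC surrogate (window 2048, contexts
#' 256/256, 6 layers of 128 filters, kernel 16, tanh encoder / sigmoid
#' decoder) and the three ANF surrogates (window 8192, contexts 7936/256,
#' 28 layers of 64 filters, kernel 8; PReLU/PReLU for the high- and
#' medium-SR fibers, tanh/sigmoid for the low-SR fiber).
#'
#' @return named list of [surrogate_spec()]: `ihc`, `anf_h`, `anf_m`, `anf_l`.
#' @export
preset_specs <- function() {
  list(
    ihc   = surrogate_spec(2048, 256, 256, 6, 128, 16, "tanh", "sigmoid"),
    anf_h = surrogate_spec(8192, 7936, 256, 28, 64, 8, "prelu", "prelu"),
    anf_m = surrogate_spec(8192, 7936, 256, 28, 64, 8, "prelu", "prelu"),
    anf_l = surrogate_spec(8192, 7936, 256, 28, 64, 8, "tanh", "sigmoid"))
}

#' Desk-scale preset architectures
#'
#' Reduced geometries with the same structure, small enough to train in
#' minutes on one CPU: an IHC-geometry surrogate (window 512, contexts 64/64,
#' 6 layers of 32 filters, kernel 16) and a shallow ANF-geometry surrogate
#' (window 512, contexts 448/64, 10 layers of 16 filters, kernel 8).
#' @export
desk_specs <- function() {
  list(
    ihc = surrogate_spec(512, 64, 64, 6, 32, 16, "tanh", "sigmoid"),
    anf = surrogate_spec(512, 448, 64, 10, 16, 8, "prelu", "prelu"))
}

# per-layer channel plan implied by the skip wiring
layer_plan <- function(spec) {
  N <- spec$n_total / 2
  F <- spec$filters
  enc <- lapply(seq_len(N), function(i)
    list(type = "conv", c_in = if (i == 1) 1L else F, c_out = F,
         act = spec$enc_act))
  dec <- lapply(seq_len(N), function(j) {
    c_in <- if (j == 1) F else 2L * F
    c_out <- if (j == N) spec$out_channels else F
    act <- if (j == N) "linear" else spec$dec_act
    list(type = "tconv", c_in = c_in, c_out = c_out, act = act)
  })
  c(enc, dec)
}

#' Closed-form count of trainable parameters
#'
#' Independent of the network code: with `N` encoder layers, `F` filters and
#' kernel `k`, the encoder holds `(k*F + F) + (N-1)*(k*F^2 + F)` parameters
#' and the decoder `(k*F^2 + F) + (N-2)*(k*2F*F + F) + (k*2F + 1)` (skip
#' concatenation doubles the input channels of decoder layers 2..N; every
#' layer has a bias).  PReLU activations add one learnable slope per filter
#' channel on every layer except the final one.
#'
#' @param spec a [surrogate_spec()].
#' @return integer parameter count.
#' @export
count_trainable_params <- function(spec) {
  N <- spec$n_total / 2
  if (N < 2) stop("architectures with fewer than 2 encoder layers are unsupported")
  k <- spec$kernel; F <- spec$filters
  enc <- (k * F + F) + (N - 1) * (k * F^2 + F)
  dec <- (k * F^2 + F) + (N - 2) * (k * 2 * F * F + F) + (k * 2 * F + 1)
  n_prelu <- sum(vapply(layer_plan(spec), function(p) {
    if (p$act == "prelu") p$c_out else 0L
  }, numeric(1)))
  as.integer(enc + dec + n_prelu)
}

#' Build a trainable surrogate network from a specification
#'
#' Encoder of stride-2 1-D convolutions with bias, decoder of stride-2
#' transposed convolutions with bias; skip connections concatenate each
#' encoder layer's post-activation output onto the matching decoder layer's
#' input (decoder layer 1 takes the bottleneck alone; the final decoder layer
#' takes a skip from encoder layer 1 and has no activation).  PReLU slopes
#' are one learnable scalar per filter channel, shared over time.  Weights
#' are initialised uniformly within +/- sqrt(1/fan_in) under `seed`.
#'
#' @param spec a [surrogate_spec()].
#' @param seed initialisation seed.
#' @param zero_init zero all weights and biases (diagnostic).
#' @return object of class `surrogate_model`.
#' @export
build_surrogate <- function(spec, seed = 1L, zero_init = FALSE) {
  plan <- layer_plan(spec)
  k <- spec$kernel
  layers <- with_local_seed(seed, lapply(plan, function(p) {
    fan_in <- k * p$c_in
    lim <- sqrt(1 / fan_in)
    nW <- if (p$type == "conv") k * p$c_in * p$c_out else k * p$c_out * p$c_in
    W <- if (zero_init) rep(0, nW) else stats::runif(nW, -lim, lim)
    W <- if (p$type == "conv") matrix(W, k * p$c_in, p$c_out)
         else matrix(W, k * p$c_out, p$c_in)
    l <- list(type = p$type, k = k, W = W, b = rep(0, p$c_out), act = p$act,
              a = NULL, c_in = p$c_in, c_out = p$c_out)
    if (p$act == "prelu") l$a <- rep(0.25, p$c_out)
    l
  }))
  structure(list(spec = spec, layers = layers), class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model: %d layers, %s parameters>\n",
              length(x$layers),
              format(introspect_params(x), big.mark = ",")))
  invisible(x)
}

#' Count parameters of a built network by introspection
#'
#' Sums the sizes of every weight, bias and PReLU-slope array actually
#' allocated; the framework-side counterpart of [count_trainable_params()].
#'
#' @param model a `surrogate_model` or `surrogate_chain`.
#' @export
introspect_params <- function(model) {
  if (inherits(model, "surrogate_chain"))
    return(sum(vapply(model$stages, introspect_params, numeric(1))))
  sum(vapply(model$layers, function(l)
    length(l$W) + length(l$b) + length(l$a), numeric(1)))
}

#' Run a surrogate over a (possibly multichannel) input window
#'
#' Applies the single-channel network independently to every CF channel
#' (weight sharing across the tonotopic axis): an input of `L_c x n_cf`
#' yields an uncropped output of `L_c x n_cf`; use [crop_context()] to remove
#' the context.  Channels are processed as a batch, so any `n_cf` works and
#' permuting input channels permutes outputs identically.
#'
#' @param model a `surrogate_model`.
#' @param x numeric matrix `L_c x n_cf` (or vector of length `L_c`).
#' @param crop also crop the context (default FALSE).
#' @return matrix of the same width.
#' @export
surrogate_predict <- function(model, x, crop = FALSE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  Tn <- nrow(x)
  N <- length(model$layers) / 2
  if (Tn %% 2^N != 0)
    stop("input length ", Tn, " must be a multiple of 2^", N, " = ", 2^N)
  ncf <- ncol(x)
  X <- matrix(as.numeric(x), ncol = 1)          # channels as batch blocks
  out <- network_forward(model, X, n_windows = ncf)$out
  y <- matrix(out, nrow = Tn, ncol = ncf)
  if (crop) y <- crop_context(y, model$spec$L_l, model$spec$L_r,
                              L = Tn - model$spec$L_l - model$spec$L_r)
  y
}

#' Extend a trained single-channel surrogate to a fixed channel count
#'
#' Returns a predictor over `time x n_cf` inputs that applies the same
#' trained weights to each of the `n_cf` channels independently (weight
#' sharing across the tonotopic axis).  Purely a convenience over
#' [surrogate_predict()], which accepts any channel count.
#'
#' @param model a trained `surrogate_model`.
#' @param n_cf number of channels the returned predictor expects.
#' @return function mapping an `L x n_cf` matrix to an `L x n_cf` matrix.
#' @export
extrapolate_channels <- function(model, n_cf) {
  stopifnot(inherits(model, "surrogate_model"), n_cf >= 1)
  function(x) {
    if (is.vector(x)) x <- matrix(x, ncol = 1)
    if (ncol(x) != n_cf)
      stop("expected ", n_cf, " channels, got ", ncol(x))
    surrogate_predict(model, x)
  }
}

#' Remove context samples from an uncropped output
#'
#' Keeps rows `[L_l + 1, L_l + L]`; errors when the input length does not
#' equal `L_l + L + L_r`.
#'
#' @param output matrix/vector of length `L_c`, or a [response_field()].
#' @param L_l,L_r context sizes (samples).
#' @param L output window; default inferred as `len - L_l - L_r`.
#' @export
crop_context <- function(output, L_l, L_r, L = NULL) {
  if (inherits(output, "response_field")) {
    v <- crop_context(output$values, L_l, L_r, L)
    return(response_field(v, output$fs, output$cf_axis, output$units))
  }
  vec <- is.vector(output)
  if (vec) output <- matrix(output, ncol = 1)
  len <- nrow(output)
  if (is.null(L)) L <- len - L_l - L_r
  if (L_l + L + L_r != len)
    stop("length mismatch: output has ", len, " samples but L_l + L + L_r = ",
         L_l + L + L_r)
  out <- output[(L_l + 1):(L_l + L), , drop = FALSE]
  if (vec) out[, 1] else out
}

#' Merge surrogate modules into a composite model
#'
#' Chains modules by feeding each stage's uncropped output (the full `L_c`
#' window, i.e. the output of the layer before cropping) into the next
#' stage's input; the composite maps the first-stage input to the last
#' stage's cropped output.  Because the convolutional weights are
#' length-agnostic, the only geometric requirements are that the shared input
#' window covers every stage's `L_c` and is divisible by every stage's total
#' stride.
#'
#' @param chain list of `surrogate_model`s (upstream first).
#' @return object of class `surrogate_chain` with a parameter count equal to
#'   the sum of the stage counts.
#' @export
merge_modules <- function(chain) {
  stopifnot(length(chain) >= 1,
            all(vapply(chain, inherits, logical(1), "surrogate_model")))
  structure(list(stages = chain), class = "surrogate_chain")
}

#' @export
print.surrogate_chain <- function(x, ...) {
  cat(sprintf("<surrogate_chain: %d stages, %s parameters>\n",
              length(x$stages),
              format(introspect_params(x), big.mark = ",")))
  invisible(x)
}

#' Run a merged chain over an input window
#'
#' @param chain a `surrogate_chain`.
#' @param x input matrix `len x n_cf` (or vector); `len` must be at least the
#'   largest stage `L_c` and divisible by the largest stage total stride.
#' @param crop crop the final output with the last stage's contexts.
#' @export
chain_predict <- function(chain, x, crop = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  len <- nrow(x)
  need_lc <- max(vapply(chain$stages, function(s) s$spec$L_c, numeric(1)))
  need_div <- max(vapply(chain$stages, function(s) 2^(s$spec$n_total / 2),
                         numeric(1)))
  if (len < need_lc || len %% need_div != 0)
    stop("insufficient upstream context: chain input of ", len,
         " samples must be >= ", need_lc, " and a multiple of ", need_div)
  for (s in chain$stages) x <- surrogate_predict(s, x, crop = FALSE)
  if (crop) {
    last <- chain$stages[[length(chain$stages)]]$spec
    x <- crop_context(x, last$L_l, last$L_r, L = len - last$L_l - last$L_r)
  }
  x
}

#' Save / load a surrogate model
#'
#' Weights go to a native-R serialisation file; a framework-neutral JSON
#' manifest (`<path>.json`) records the specification, every weight-array
#' shape and a content hash for integrity checks.
#'
#' @param model a `surrogate_model`.
#' @param path output file path.
#' @export
save_surrogate <- function(model, path) {
  saveRDS(model, path)
  shapes <- lapply(model$layers, function(l)
    list(type = l$type, W = dim(l$W), b = length(l$b),
         a = if (is.null(l$a)) 0 else length(l$a), act = l$act))
  hash <- sum(vapply(model$layers, function(l) sum(l$W) + sum(l$b), numeric(1)))
  jsonlite::write_json(
    list(spec = unclass(model$spec), shapes = shapes,
         n_params = introspect_params(model), checksum = hash),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "surrogate_model"))
  model
}
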