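#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param loss `"L1"` (mean absolute error) or `"L1_time_plus_spectrum"`
#'   (adds the L1 distance between magnitude spectra; used by the stimulus
#'   preprocessor).
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param seed RNG seed covering initialisation, the validation split and
#'   shuffling.
#' @param patience early-stopping patience in epochs (validation L1);
#'   `Inf` disables early stopping.
#' @param val_fraction held-out validation fraction (default 0.1).
#' @param lr_decay multiplicative step-decay factor applied to the learning
#'   rate every `decay_every` epochs (1 = constant rate).
#' @param decay_every epochs between decay steps.
#' @export
train_config <- function(learning_rate = 1e-4, loss = "L1", epochs = 100,
                         batch_size = 32, seed = 1L, patience = Inf,
                         val_fraction = 0.1, lr_decay = 1, decay_every = 50) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            val_fraction >= 0, val_fraction < 1, lr_decay > 0, lr_decay <= 1,
            decay_every >= 1)
  loss <- match.arg(loss, c("L1", "L1_time_plus_spectrum"))
  structure(list(learning_rate = learning_rate, loss = loss, epochs = epochs,
                 batch_size = batch_size, seed = seed, patience = patience,
                 val_fraction = val_fraction, lr_decay = lr_decay,
                 decay_every = decay_every),
            class = "train_config")
}

#' Mean absolute error (L1 loss)
#'
#' @param pred,target equal-shape numeric arrays.
#' @export
l1_loss <- function(pred, target) {
  if (length(pred) != length(target)) stop("shape mismatch in l1_loss")
  mean(abs(pred - target))
}

# forward a batch of windows through a net; returns per-window output matrix
batch_forward <- function(net, inputs_mat) {
  B <- nrow(inputs_mat)
  L_c <- ncol(inputs_mat)
  X <- matrix(as.numeric(t(inputs_mat)), ncol = 1)
  fw <- network_forward(net, X, n_windows = B)
  list(pred = matrix(fw$out, nrow = L_c, ncol = B), caches = fw$caches, B = B)
}

# mean |pred - target| over the cropped region of a batch
batch_val_loss <- function(net, ws, idx) {
  spec <- net$spec
  tot <- 0
  for (i in idx) {
    fw <- batch_forward(net, ws$inputs[i, , drop = FALSE])
    pred <- fw$pred[(spec$L_l + 1):(spec$L_l + spec$L), 1]
    tot <- tot + mean(abs(pred - ws$targets[i, ]))
  }
  tot / length(idx)
}

#' Train a surrogate network on a window set
#'
#' Minibatch Adam on the L1 loss between the cropped network output and the
#' target windows, with a seeded 90/10 train/validation split, optional early
#' stopping on validation L1, and best-checkpoint selection.  Aborts with the
#' last good checkpoint if the loss turns non-finite.  Two runs with the same
#' seed give identical loss histories.
#'
#' @param spec a [surrogate_spec()].
#' @param window_set a [training_window_set()] matching `spec`'s geometry.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best checkpoint), `history` (data.frame of
#'   epoch/train/validation L1), `best_epoch`.
#' @export
train_surrogate <- function(spec, window_set, config = train_config(),
                            verbose = FALSE) {
  stopifnot(inherits(window_set, "training_window_set"),
            ncol(window_set$inputs) == spec$L_c,
            ncol(window_set$targets) == spec$L)
  n <- nrow(window_set$inputs)
  net <- build_surrogate(spec, seed = config$seed)
  state <- adam_state(net)
  with_local_seed(config$seed + 1L, {
    perm <- sample.int(n)
    n_val <- max(if (config$val_fraction > 0) 1 else 0,
                 floor(config$val_fraction * n))
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(loss = Inf, layers = net$layers, epoch = 0L)
    t_step <- 0
    diverged <- FALSE
    crop_rows <- (spec$L_l + 1):(spec$L_l + spec$L)
    for (epoch in seq_len(config$epochs)) {
      lr_epoch <- config$learning_rate *
        config$lr_decay^((epoch - 1) %/% config$decay_every)
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bidx in batches) {
        fw <- batch_forward(net, window_set$inputs[bidx, , drop = FALSE])
        tgt <- t(window_set$targets[bidx, , drop = FALSE])   # L x B
        pred <- fw$pred[crop_rows, , drop = FALSE]
        loss <- mean(abs(pred - tgt))
        if (!is.finite(loss)) {
          warning("training diverged (non-finite loss); returning last good checkpoint")
          diverged <- TRUE
          break
        }
        ep_loss <- ep_loss + loss * length(bidx)
        dPred <- sign(pred - tgt) / length(pred)
        dOut <- matrix(0, spec$L_c, length(bidx))
        dOut[crop_rows, ] <- dPred
        dOut <- matrix(as.numeric(dOut), ncol = 1)
        bk <- network_backward(net, fw$caches, dOut, n_windows = length(bidx))
        t_step <- t_step + 1
        st <- adam_step(net, bk$grads, state, lr_epoch, t_step)
        net <- st$net; state <- st$state
      }
      if (diverged) break
      ep_loss <- ep_loss / length(tr_idx)
      vl <- if (length(val_idx)) batch_val_loss(net, window_set, val_idx)
            else ep_loss
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                           val_loss = vl))
      if (verbose) message(sprintf("epoch %3d  train %.5f  val %.5f",
                                   epoch, ep_loss, vl))
      if (vl < best$loss) best <- list(loss = vl, layers = net$layers,
                                       epoch = epoch)
      if (is.finite(config$patience) &&
          epoch - best$epoch >= config$patience) break
    }
    net$layers <- best$layers
    list(model = net, history = history, best_epoch = best$epoch,
         diverged = diverged)
  })
}

#' Scale a firing-rate field by a fiber population count
#'
#' Pointwise multiplication by `n_fibers` (linear: the population rate of n
#' identical fibers).
#'
#' @param rate_field [response_field()], matrix or vector.
#' @param n_fibers non-negative count.
#' @export
scale_population <- function(rate_field, n_fibers) {
  stopifnot(n_fibers >= 0)
  if (inherits(rate_field, "response_field")) {
    return(response_field(rate_field$values * n_fibers, rate_field$fs,
                          rate_field$cf_axis, rate_field$units))
  }
  rate_field * n_fibers
}

# forward through a frozen chain keeping caches (for input gradients)
chain_forward_caches <- function(chain, X, n_windows) {
  caches <- vector("list", length(chain$stages))
  for (i in seq_along(chain$stages)) {
    fw <- network_forward(chain$stages[[i]], X, n_windows)
    caches[[i]] <- fw$caches
    X <- fw$out
  }
  list(out = X, caches = caches)
}

chain_backward_input <- function(chain, caches, dOut, n_windows) {
  for (i in rev(seq_along(chain$stages))) {
    dOut <- network_backward(chain$stages[[i]], caches[[i]], dOut,
                             n_windows)$dx
  }
  dOut
}

# gradient of mean | |F(y)| - |F(ref)| | with respect to y
spectrum_l1_grad <- function(y, ref_mag) {
  Y <- stats::fft(y)
  K <- length(y)
  w <- sign(Mod(Y) - ref_mag) / K
  Re(stats::fft(w * Conj(Y) / pmax(Mod(Y), 1e-12)))
}

#' Train a stimulus preprocessor by backpropagating through frozen models
#'
#' Trains a small network `P` so that the pathological chain driven by
#' `P(x)` reproduces the normal chain driven by `x`: both chains are frozen;
#' gradients flow through the pathological chain into `P`.  The loss is the
#' L1 distance between the time traces plus the L1 distance between their
#' magnitude spectra.  The corpus convention follows the restoration demo:
#' 4-kHz tones of varied levels and modulation depths, normalised to the
#' amplitude range of the first chain stage's input.
#'
#' @param normal_model,pathological_model `surrogate_chain`s (see
#'   [merge_modules()]); outputs are scaled by `n_normal`/`n_patho` fibers.
#' @param corpus matrix of input windows (rows), in chain-input units.
#' @param config a [train_config()] (loss `"L1_time_plus_spectrum"`).
#' @param pre_spec [surrogate_spec()] of the preprocessor; default a 4-layer
#'   net over the full chain input with no context.
#' @param n_normal,n_patho population multipliers (default 10 and 8: a 20%
#'   fiber deafferentation of 10 fibers).
#' @return list with `preprocessor`, `history`, `baseline_loss` (unprocessed
#'   input), `final_loss`.
#' @export
optimize_stimulus_preprocessor <- function(normal_model, pathological_model,
                                           corpus, config = train_config(
                                             learning_rate = 1e-3,
                                             loss = "L1_time_plus_spectrum",
                                             epochs = 60),
                                           pre_spec = NULL,
                                           n_normal = 10, n_patho = 8) {
  stopifnot(inherits(normal_model, "surrogate_chain"),
            inherits(pathological_model, "surrogate_chain"),
            is.matrix(corpus))
  len <- ncol(corpus)
  last <- pathological_model$stages[[length(pathological_model$stages)]]$spec
  crop_rows <- (last$L_l + 1):(last$L_l + (len - last$L_l - last$L_r))
  if (is.null(pre_spec)) {
    pre_spec <- surrogate_spec(L = len, L_l = 0, L_r = 0, n_total = 4,
                               filters = 8, kernel = 16, "tanh", "tanh")
  }
  P <- build_surrogate(pre_spec, seed = config$seed)
  state <- adam_state(P)
  # frozen targets: normal-chain responses to the raw corpus
  targets <- lapply(seq_len(nrow(corpus)), function(i) {
    y <- chain_predict(normal_model, corpus[i, ], crop = TRUE)[, 1] * n_normal
    list(y = y, mag = Mod(stats::fft(y)))
  })
  eval_loss <- function(xhat_mat) {
    tot <- 0
    for (i in seq_len(nrow(corpus))) {
      yh <- chain_predict(pathological_model, xhat_mat[i, ],
                          crop = TRUE)[, 1] * n_patho
      tot <- tot + mean(abs(yh - targets[[i]]$y)) +
        mean(abs(Mod(stats::fft(yh)) - targets[[i]]$mag))
    }
    tot / nrow(corpus)
  }
  baseline <- eval_loss(corpus)
  history <- numeric(0)
  t_step <- 0
  with_local_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      ep <- 0
      for (i in sample(nrow(corpus))) {
        x <- matrix(corpus[i, ], ncol = 1)
        fwP <- network_forward(P, x, 1L)
        xhat <- fwP$out
        fwC <- chain_forward_caches(pathological_model, xhat, 1L)
        yh <- fwC$out[crop_rows, 1] * n_patho
        tg <- targets[[i]]
        lt <- mean(abs(yh - tg$y))
        ls <- mean(abs(Mod(stats::fft(yh)) - tg$mag))
        ep <- ep + lt + ls
        dy <- sign(yh - tg$y) / length(yh) + spectrum_l1_grad(yh, tg$mag)
        dOut <- matrix(0, len, 1)
        dOut[crop_rows, 1] <- dy * n_patho
        dxhat <- chain_backward_input(pathological_model, fwC$caches, dOut, 1L)
        bk <- network_backward(P, fwP$caches, dxhat, 1L)
        t_step <- t_step + 1
        st <- adam_step(P, bk$grads, state, config$learning_rate, t_step)
        P <- st$net; state <- st$state
      }
      history <- c(history, ep / nrow(corpus))
    }
  })
  xhat_mat <- t(vapply(seq_len(nrow(corpus)), function(i)
    network_forward(P, matrix(corpus[i, ], ncol = 1), 1L)$out[, 1],
    numeric(len)))
  list(preprocessor = P, history = history, baseline_loss = baseline,
       final_loss = eval_loss(xhat_mat))
}
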