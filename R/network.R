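# Internal 1-D convolutional network engine.
#
# A batch of B windows, each T samples x C channels, is stored as a
# (B*T) x C matrix of stacked row blocks.  Strided (stride-2) convolutions
# halve T exactly and transposed convolutions double it exactly; padding is
# "same"-style with total pad k - 2 split left-heavy-symmetrically
# (floor((k-2)/2) on the left).  Transposed convolutions are implemented as
# the exact adjoint of the gather used by the forward convolution, which
# guarantees the 2x length contract and makes backprop a mirror image of the
# forward pass.  All heavy lifting is BLAS matrix products on im2col views.

conv_geometry <- function(T_in, B, k, transposed = FALSE) {
  # geometry of the conv that maps length 2*T_out -> T_out; for a forward
  # conv T_out = T_in / 2, for a tconv the roles are swapped (T_out = T_in)
  T_long <- if (transposed) 2L * T_in else T_in
  T_short <- T_long %/% 2L
  pad_total <- k - 2L
  pad_l <- pad_total %/% 2L
  Tp <- T_long + pad_total
  base <- rep((0:(B - 1L)) * Tp, each = T_short) + (0:(T_short - 1L)) * 2L
  rows_p <- rep((0:(B - 1L)) * Tp, each = T_long) + pad_l + seq_len(T_long)
  list(T_long = T_long, T_short = T_short, Tp = Tp, k = k, B = B,
       base = base, rows_p = rows_p)
}

im2col <- function(Xp, geo, C) {
  m <- length(geo$base)
  out <- matrix(0, m, geo$k * C)
  for (j in seq_len(geo$k)) {
    out[, ((j - 1L) * C + 1L):(j * C)] <- Xp[geo$base + j, , drop = FALSE]
  }
  out
}

col2im_add <- function(dXcol, geo, C) {
  dXp <- matrix(0, geo$B * geo$Tp, C)
  for (j in seq_len(geo$k)) {
    rows <- geo$base + j
    dXp[rows, ] <- dXp[rows, ] + dXcol[, ((j - 1L) * C + 1L):(j * C),
                                       drop = FALSE]
  }
  dXp
}

pad_blocks <- function(X, geo) {
  Xp <- matrix(0, geo$B * geo$Tp, ncol(X))
  Xp[geo$rows_p, ] <- X
  Xp
}

# activations -----------------------------------------------------------------

act_forward <- function(layer, Z) {
  switch(layer$act,
    linear  = Z,
    tanh    = tanh(Z),
    sigmoid = 1 / (1 + exp(-Z)),
    prelu   = pmax(Z, 0) + sweep(pmin(Z, 0), 2, layer$a, "*"),
    stop("unknown activation: ", layer$act))
}

act_backward <- function(layer, Z, A, dA) {
  switch(layer$act,
    linear  = list(dZ = dA, da = NULL),
    tanh    = list(dZ = dA * (1 - A^2), da = NULL),
    sigmoid = list(dZ = dA * A * (1 - A), da = NULL),
    prelu   = {
      neg <- Z < 0
      slope <- matrix(1, nrow(Z), ncol(Z))
      slope[neg] <- rep(layer$a, each = nrow(Z))[neg]
      list(dZ = dA * slope, da = colSums(dA * pmin(Z, 0)))
    })
}

# layers ----------------------------------------------------------------------

layer_forward <- function(layer, X, T_in, B) {
  C <- ncol(X)
  if (layer$type == "conv") {
    geo <- conv_geometry(T_in, B, layer$k, transposed = FALSE)
    Xcol <- im2col(pad_blocks(X, geo), geo, C)
    Z <- Xcol %*% layer$W
    Z <- Z + rep(layer$b, each = nrow(Z))
    A <- act_forward(layer, Z)
    list(out = A, T_out = geo$T_short,
         cache = list(Xcol = Xcol, Z = Z, A = A, geo = geo, C = C))
  } else {
    geo <- conv_geometry(T_in, B, layer$k, transposed = TRUE)
    Cout <- length(layer$b)
    Xcol_t <- tcrossprod(X, layer$W)           # (B*T_in) x (k*Cout)
    Yp <- col2im_add(Xcol_t, geo, Cout)
    Z <- Yp[geo$rows_p, , drop = FALSE]
    Z <- Z + rep(layer$b, each = nrow(Z))
    A <- act_forward(layer, Z)
    list(out = A, T_out = geo$T_long,
         cache = list(X = X, Z = Z, A = A, geo = geo, C = C))
  }
}

layer_backward <- function(layer, cache, dA) {
  ab <- act_backward(layer, cache$Z, cache$A, dA)
  dZ <- ab$dZ
  if (layer$type == "conv") {
    geo <- cache$geo
    dW <- crossprod(cache$Xcol, dZ)
    db <- colSums(dZ)
    dXcol <- tcrossprod(dZ, layer$W)
    dXp <- col2im_add(dXcol, geo, cache$C)
    dX <- dXp[geo$rows_p, , drop = FALSE]
  } else {
    geo <- cache$geo
    db <- colSums(dZ)
    dZp <- pad_blocks(dZ, geo)
    dZcol <- im2col(dZp, geo, length(layer$b))
    dX <- dZcol %*% layer$W
    dW <- crossprod(dZcol, cache$X)
  }
  list(dx = dX, dW = dW, db = db, da = ab$da)
}

# sequential (no-skip) helpers, used by the gradient-support oracle ----------

network_forward_layers <- function(layers, X, n_windows) {
  T_in <- nrow(X) / n_windows
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], X, T_in, n_windows)
    caches[[i]] <- fw$cache
    X <- fw$out
    T_in <- fw$T_out
  }
  list(out = X, caches = caches)
}

network_backward_layers <- function(layers, caches, dOut, n_windows) {
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], caches[[i]], dOut)
    dOut <- bk$dx
  }
  list(dx = dOut)
}

# full encoder-decoder with skip concatenation -------------------------------
#
# Decoder layer 1 receives the bottleneck alone; decoder layer j >= 2 receives
# the channel-concatenation of decoder layer j-1's output and encoder layer
# (N - j + 1)'s post-activation output; the final decoder layer maps to the
# output channels with no activation.

network_forward <- function(net, X, n_windows) {
  N <- length(net$layers) / 2L
  T_in <- nrow(X) / n_windows
  enc_out <- vector("list", N)
  caches <- vector("list", 2L * N)
  for (i in seq_len(N)) {
    fw <- layer_forward(net$layers[[i]], X, T_in, n_windows)
    caches[[i]] <- fw$cache
    X <- fw$out
    T_in <- fw$T_out
    enc_out[[i]] <- X
  }
  for (j in seq_len(N)) {
    inp <- if (j == 1) X else cbind(X, enc_out[[N - j + 1L]])
    fw <- layer_forward(net$layers[[N + j]], inp, T_in, n_windows)
    caches[[N + j]] <- fw$cache
    X <- fw$out
    T_in <- fw$T_out
  }
  list(out = X, caches = caches)
}

network_backward <- function(net, caches, dOut, n_windows) {
  N <- length(net$layers) / 2L
  grads <- vector("list", 2L * N)
  skip_grad <- vector("list", N)      # accumulated gradients on encoder outputs
  for (j in rev(seq_len(N))) {
    bk <- layer_backward(net$layers[[N + j]], caches[[N + j]], dOut)
    grads[[N + j]] <- bk[c("dW", "db", "da")]
    if (j == 1) {
      dOut <- bk$dx
    } else {
      F_dec <- ncol(bk$dx) - ncol(skip_grad_target(caches, N, j))
      dOut <- bk$dx[, seq_len(F_dec), drop = FALSE]
      sk <- bk$dx[, (F_dec + 1L):ncol(bk$dx), drop = FALSE]
      idx <- N - j + 1L
      skip_grad[[idx]] <- if (is.null(skip_grad[[idx]])) sk
                          else skip_grad[[idx]] + sk
    }
  }
  # dOut now holds the gradient on the bottleneck (encoder layer N output)
  for (i in rev(seq_len(N))) {
    if (!is.null(skip_grad[[i]])) dOut <- dOut + skip_grad[[i]]
    bk <- layer_backward(net$layers[[i]], caches[[i]], dOut)
    grads[[i]] <- bk[c("dW", "db", "da")]
    dOut <- bk$dx
  }
  list(grads = grads, dx = dOut)
}

# channel count of the encoder output concatenated at decoder layer j
skip_grad_target <- function(caches, N, j) {
  caches[[N - j + 1L]]$A
}

# Adam ------------------------------------------------------------------------

adam_state <- function(net) {
  lapply(net$layers, function(l) {
    s <- list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    if (!is.null(l$a)) { s$ma <- l$a * 0; s$va <- l$a * 0 }
    s
  })
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    u <- upd(net$layers[[i]]$W, g$dW, state[[i]]$mW, state[[i]]$vW)
    net$layers[[i]]$W <- u$p; state[[i]]$mW <- u$m; state[[i]]$vW <- u$v
    u <- upd(net$layers[[i]]$b, g$db, state[[i]]$mb, state[[i]]$vb)
    net$layers[[i]]$b <- u$p; state[[i]]$mb <- u$m; state[[i]]$vb <- u$v
    if (!is.null(net$layers[[i]]$a) && !is.null(g$da)) {
      u <- upd(net$layers[[i]]$a, g$da, state[[i]]$ma, state[[i]]$va)
      net$layers[[i]]$a <- u$p; state[[i]]$ma <- u$m; state[[i]]$va <- u$v
    }
  }
  list(net = net, state = state)
}
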