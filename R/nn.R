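# Internal neural-network engine: forward, backward and Adam for the
# embedding -> conv1d -> maxpool -> BiLSTM -> dense -> dense graph and its
# layer-removal variants. Everything is plain matrix arithmetic arranged as
# few large BLAS calls: the convolution is one im2col GEMM, the LSTM input
# projections for all time steps are batched, and pooling is vectorized
# over time.
#
# Conventions:
#   X      integer code matrix, n x L, values 0..4 (row = one encoded pair)
#   arrays (n, time, channels), column-major; array(A, c(n*T, C)) therefore
#          reinterprets (b, t, c) as row b + (t-1)n without copying logic
#   conv   "valid" boundary mode: output length L - I + 1 (the convolution
#          sum only covers in-bounds positions)

sigmoid <- function(z) 1 / (1 + exp(-z))
relu <- function(z) { z[z < 0] <- 0; z }

# column indices into the n x (L*d) embedded matrix for each conv window;
# row layout of the kernel matrix is (channel j - 1)*I + position i
conv_col_index <- function(L, I, d) {
  idx <- matrix(0L, nrow = L - I + 1L, ncol = I * d)
  for (m in seq_len(L - I + 1L)) {
    for (j in seq_len(d)) {
      idx[m, (j - 1L) * I + seq_len(I)] <- (m + seq_len(I) - 2L) + (j - 1L) * L + 1L
    }
  }
  idx
}

dropout_mask <- function(dim_vec, p) {
  if (p <= 0) return(NULL)
  array((stats::runif(prod(dim_vec)) >= p) / (1 - p), dim = dim_vec)
}

# One LSTM direction over input array Xarr (n, T, C), time steps processed
# in `ord`. The input projection x_t W is computed for all steps in one
# GEMM. Returns the final hidden state plus the per-step caches needed for
# backprop-through-time (gate activations, cell states, hidden states).
lstm_forward <- function(Xarr, W, V, b, H, act = "relu", reverse = FALSE) {
  n <- dim(Xarr)[1L]; Tn <- dim(Xarr)[2L]; C <- dim(Xarr)[3L]
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  Xmat <- Xarr; dim(Xmat) <- c(n * Tn, C)
  XW <- Xmat %*% W                     # (n*T) x 4H, rows b + (t-1)n
  brow <- rep(b, each = n)
  i_l <- f_l <- g_l <- o_l <- c_l <- h_l <- vector("list", Tn)
  h <- matrix(0, n, H); cs <- matrix(0, n, H)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (s in seq_len(Tn)) {
    rows <- (ord[s] - 1L) * n + seq_len(n)
    z <- XW[rows, , drop = FALSE] + h %*% V + brow
    i <- sigmoid(z[, i1, drop = FALSE])
    f <- sigmoid(z[, i2, drop = FALSE])
    g <- tanh(z[, i3, drop = FALSE])
    o <- sigmoid(z[, i4, drop = FALSE])
    cs <- f * cs + i * g
    hc <- if (act == "relu") relu(cs) else tanh(cs)
    h <- o * hc
    i_l[[s]] <- i; f_l[[s]] <- f; g_l[[s]] <- g; o_l[[s]] <- o
    c_l[[s]] <- cs; h_l[[s]] <- h
  }
  list(h_last = h, i = i_l, f = f_l, g = g_l, o = o_l, c = c_l, h = h_l,
       ord = ord, act = act, Xmat = Xmat, n = n, Tn = Tn)
}

# Backprop one direction given the gradient wrt its final hidden state.
lstm_backward <- function(cache, W, V, dh_last) {
  n <- cache$n; Tn <- cache$Tn; H <- ncol(dh_last)
  tW <- t(W); tV <- t(V)
  dV <- matrix(0, H, 4L * H); db <- numeric(4L * H)
  dZall <- matrix(0, n * Tn, 4L * H)   # rows follow cache$Xmat layout
  dh <- dh_last; dc <- matrix(0, n, H)
  zero <- matrix(0, n, H)
  for (s in rev(seq_len(Tn))) {
    i <- cache$i[[s]]; f <- cache$f[[s]]; g <- cache$g[[s]]
    o <- cache$o[[s]]; cs <- cache$c[[s]]
    hc <- if (cache$act == "relu") relu(cs) else tanh(cs)
    dact <- if (cache$act == "relu") (cs > 0) + 0 else 1 - hc^2
    do <- dh * hc
    dc <- dc + dh * o * dact
    di <- dc * g; dg <- dc * i
    cprev <- if (s > 1L) cache$c[[s - 1L]] else zero
    df <- dc * cprev
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do * o * (1 - o))
    hprev <- if (s > 1L) cache$h[[s - 1L]] else zero
    dV <- dV + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dZall[(cache$ord[s] - 1L) * n + seq_len(n), ] <- dz
    dh <- dz %*% tV
    dc <- dc * f
  }
  dW <- crossprod(cache$Xmat, dZall)
  dXmat <- dZall %*% tW
  dim(dXmat) <- c(n, Tn, ncol(tW))
  list(dW = dW, dV = dV, db = db, dXarr = dXmat)
}

# Full forward pass. When training = TRUE, dropout masks are drawn from the
# current RNG state and kept in the cache for the backward pass.
nn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec; w <- model$weights
  n <- nrow(X); L <- ncol(X)
  if (L != spec$input_len) {
    stop(sprintf("input length %d does not match model input_len %d",
                 L, spec$input_len), call. = FALSE)
  }
  p <- if (training && spec$dropout_active) spec$dropout_rate else 0
  cache <- list(X = X, n = n)

  Memb <- w$E[as.vector(X) + 1L, , drop = FALSE]
  dim(Memb) <- c(n, L * spec$embed_dim)

  if (spec$has_conv) {
    Lc <- L - spec$kernel_size + 1L
    K <- spec$n_kernels
    Cbig <- Memb[, as.vector(model$colidx), drop = FALSE]
    dim(Cbig) <- c(n * Lc, spec$kernel_size * spec$embed_dim)
    Z <- relu(Cbig %*% w$Wc + rep(w$bc, each = n * Lc))
    cache$Cbig <- Cbig
    A <- Z; dim(A) <- c(n, Lc, K)
    cache$Aconv <- A
    mk <- dropout_mask(dim(A), p)
    if (!is.null(mk)) { A <- A * mk; cache$mk_conv <- mk }
    cur <- A
  } else {
    cur <- array(Memb, dim = c(n, L, spec$embed_dim))
  }
  cache$Memb <- Memb

  if (spec$has_pool) {
    ps <- spec$pool_size; st <- spec$pool_stride
    Tc <- dim(cur)[2L]
    Tp <- (Tc - ps) %/% st + 1L
    starts <- (seq_len(Tp) - 1L) * st + 1L
    P <- cur[, starts, , drop = FALSE]
    argm <- array(1L, dim = dim(P))
    if (ps > 1L) for (q in 2L:ps) {
      sl <- cur[, starts + q - 1L, , drop = FALSE]
      upd <- sl > P
      P[upd] <- sl[upd]
      argm[upd] <- q
    }
    cache$pool_arg <- argm; cache$pool_in_dim <- dim(cur)
    cache$pool_starts <- starts
    mk <- dropout_mask(dim(P), p)
    if (!is.null(mk)) { P <- P * mk; cache$mk_pool <- mk }
    cur <- P
  }
  cache$Xr <- cur  # input to the recurrent (or flattened dense) stage

  if (spec$has_rnn) {
    fw <- lstm_forward(cur, w$Wf, w$Vf, w$bf, spec$rnn_units,
                       spec$rnn_activation, reverse = FALSE)
    bw <- lstm_forward(cur, w$Wb, w$Vb, w$bb, spec$rnn_units,
                       spec$rnn_activation, reverse = TRUE)
    feat <- cbind(fw$h_last, bw$h_last)
    cache$lstm_fw <- fw; cache$lstm_bw <- bw
    mk <- dropout_mask(dim(feat), p)
    if (!is.null(mk)) { feat <- feat * mk; cache$mk_rnn <- mk }
  } else {
    feat <- cur; dim(feat) <- c(n, prod(dim(cur)[-1L]))
  }
  cache$feat <- feat

  if (spec$has_dense_hidden) {
    A1 <- relu(feat %*% w$W1 + rep(w$b1, each = n))
    cache$A1 <- A1
    mk <- dropout_mask(dim(A1), p)
    if (!is.null(mk)) { A1 <- A1 * mk; cache$mk_d1 <- mk }
    cache$A1d <- A1
    z2 <- A1 %*% w$W2 + w$b2
  } else {
    z2 <- feat %*% w$W2 + w$b2
  }
  prob <- sigmoid(pmin(pmax(z2, -30), 30))
  cache$prob <- prob
  list(prob = as.vector(prob), cache = cache)
}

# Backward pass for mean binary cross-entropy; returns gradients named like
# the weight list.
nn_backward <- function(model, cache, y) {
  spec <- model$spec; w <- model$weights
  n <- cache$n
  g <- list()
  dz2 <- (cache$prob - y) / n  # d(BCE)/d(pre-sigmoid)

  if (spec$has_dense_hidden) {
    g$W2 <- crossprod(cache$A1d, dz2)
    g$b2 <- sum(dz2)
    dA1 <- dz2 %*% t(w$W2)
    if (!is.null(cache$mk_d1)) dA1 <- dA1 * cache$mk_d1
    dz1 <- dA1 * (cache$A1 > 0)
    g$W1 <- crossprod(cache$feat, dz1)
    g$b1 <- colSums(dz1)
    dfeat <- dz1 %*% t(w$W1)
  } else {
    g$W2 <- crossprod(cache$feat, dz2)
    g$b2 <- sum(dz2)
    dfeat <- dz2 %*% t(w$W2)
  }

  if (spec$has_rnn) {
    if (!is.null(cache$mk_rnn)) dfeat <- dfeat * cache$mk_rnn
    H <- spec$rnn_units
    bk_f <- lstm_backward(cache$lstm_fw, w$Wf, w$Vf,
                          dfeat[, seq_len(H), drop = FALSE])
    bk_b <- lstm_backward(cache$lstm_bw, w$Wb, w$Vb,
                          dfeat[, H + seq_len(H), drop = FALSE])
    g$Wf <- bk_f$dW; g$Vf <- bk_f$dV; g$bf <- bk_f$db
    g$Wb <- bk_b$dW; g$Vb <- bk_b$dV; g$bb <- bk_b$db
    dcur <- bk_f$dXarr + bk_b$dXarr
  } else {
    dcur <- array(dfeat, dim = dim(cache$Xr))
  }

  if (spec$has_pool) {
    if (!is.null(cache$mk_pool)) dcur <- dcur * cache$mk_pool
    ps <- spec$pool_size
    starts <- cache$pool_starts
    dA <- array(0, dim = cache$pool_in_dim)
    for (q in seq_len(ps)) {
      sel <- cache$pool_arg == q
      if (any(sel)) {
        tgt <- dA[, starts + q - 1L, , drop = FALSE]
        tgt[sel] <- tgt[sel] + dcur[sel]
        dA[, starts + q - 1L, ] <- tgt
      }
    }
    dcur <- dA
  }

  L <- spec$input_len
  if (spec$has_conv) {
    if (!is.null(cache$mk_conv)) dcur <- dcur * cache$mk_conv
    Lc <- dim(cache$Aconv)[2L]
    dZ <- dcur * (cache$Aconv > 0)
    dim(dZ) <- c(n * Lc, spec$n_kernels)
    g$Wc <- crossprod(cache$Cbig, dZ)
    g$bc <- colSums(dZ)
    dCbig <- dZ %*% t(w$Wc)            # (n*Lc) x (I*d)
    dim(dCbig) <- c(n, Lc * spec$kernel_size * spec$embed_dim)
    dMemb <- matrix(0, n, L * spec$embed_dim)
    for (m in seq_len(Lc)) {
      cols <- (seq_len(spec$kernel_size * spec$embed_dim) - 1L) * Lc + m
      idx <- model$colidx[m, ]
      dMemb[, idx] <- dMemb[, idx] + dCbig[, cols, drop = FALSE]
    }
  } else {
    dMemb <- matrix(dcur, n, L * spec$embed_dim)
  }

  dM2 <- dMemb
  dim(dM2) <- c(n * L, spec$embed_dim)
  codes <- as.vector(cache$X)
  g$E <- matrix(0, spec$vocab_size, spec$embed_dim)
  acc <- rowsum(dM2, group = codes)
  g$E[sort(unique(codes)) + 1L, ] <- acc
  g
}

bce_loss <- function(y, prob) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(x) x * 0),
       v = lapply(weights, function(x) x * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}
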