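# Internal neural-network math: 1-D convolution stacks via im2col, mean
# pooling, bidirectional LSTM, softmax cross-entropy, and Adam. Everything
# is plain matrix algebra so training is deterministic given the RNG seed
# and runs on one CPU core.
#
# Data layout: a batch of windows is a matrix Hm of shape (N*P, C) where N
# is the number of windows, P the number of positions (time samples) and C
# channels; row index = n + (p-1)*N (window index varies fastest).

.pos_rows <- function(positions, N) {
  # row indices of the given positions for all N windows, window-fastest
  as.vector(outer(seq_len(N), (positions - 1L) * N, `+`))
}

.im2col <- function(Hm, N, P, C, k) {
  Pout <- P - k + 1L
  M <- matrix(0, N * Pout, k * C)
  for (kk in seq_len(k)) {
    rows <- .pos_rows(seq.int(kk, length.out = Pout), N)
    for (ch in seq_len(C)) M[, (ch - 1L) * k + kk] <- Hm[rows, ch]
  }
  M
}

.col2im_add <- function(dM, N, P, C, k) {
  # transpose of .im2col: scatter-add column gradients back to input rows
  Pout <- P - k + 1L
  dH <- matrix(0, N * P, C)
  for (kk in seq_len(k)) {
    rows <- .pos_rows(seq.int(kk, length.out = Pout), N)
    cols <- (seq_len(C) - 1L) * k + kk
    dH[rows, ] <- dH[rows, ] + dM[, cols, drop = FALSE]
  }
  dH
}

.pool_mean <- function(Hm, N, P, C, pool) {
  Pout <- P %/% pool
  out <- matrix(0, N * Pout, C)
  for (j in seq_len(pool)) {
    rows <- .pos_rows(seq.int(j, by = pool, length.out = Pout), N)
    out <- out + Hm[rows, , drop = FALSE]
  }
  out / pool
}

.pool_mean_back <- function(dP, N, P, C, pool) {
  Pout <- P %/% pool
  dH <- matrix(0, N * P, C)
  g <- dP / pool
  for (j in seq_len(pool)) {
    rows <- .pos_rows(seq.int(j, by = pool, length.out = Pout), N)
    dH[rows, ] <- g
  }
  dH
}

# ---- convolutional feature extractor ---------------------------------------

cnn_out_channels <- function(cfg) cfg$conv_channels[length(cfg$conv_channels)]

cnn_forward <- function(params, cfg, Xm, N, keep_cache = FALSE) {
  H <- Xm
  P <- 100L
  C <- 3L
  cache <- list()
  for (l in seq_along(cfg$conv_channels)) {
    W <- params[[paste0("conv", l, "_W")]]
    b <- params[[paste0("conv", l, "_b")]]
    M <- .im2col(H, N, P, C, cfg$conv_kernel)
    Z <- sweep(M %*% W, 2, b, `+`)
    A <- Z * (Z > 0)
    Pc <- P - cfg$conv_kernel + 1L
    Hp <- .pool_mean(A, N, Pc, ncol(W), cfg$pool)
    if (keep_cache) cache[[l]] <- list(M = M, relu = Z > 0, P_in = P, C_in = C,
                                       P_conv = Pc)
    H <- Hp
    P <- Pc %/% cfg$pool
    C <- ncol(W)
  }
  # global mean over remaining positions -> one feature vector per window
  F <- matrix(0, N, C)
  for (p in seq_len(P)) F <- F + H[((p - 1L) * N + 1L):(p * N), , drop = FALSE]
  F <- F / P
  list(F = F, cache = cache, P_last = P, C_last = C)
}

cnn_backward <- function(params, cfg, fwd, dF, N) {
  P <- fwd$P_last
  C <- fwd$C_last
  dH <- matrix(0, N * P, C)
  for (p in seq_len(P))
    dH[((p - 1L) * N + 1L):(p * N), ] <- dF / P
  grads <- list()
  for (l in rev(seq_along(cfg$conv_channels))) {
    cc <- fwd$cache[[l]]
    W <- params[[paste0("conv", l, "_W")]]
    dA <- .pool_mean_back(dH, N, cc$P_conv, ncol(W), cfg$pool)
    dZ <- dA * cc$relu
    grads[[paste0("conv", l, "_W")]] <- crossprod(cc$M, dZ)
    grads[[paste0("conv", l, "_b")]] <- colSums(dZ)
    if (l > 1) {
      dM <- dZ %*% t(W)
      dH <- .col2im_add(dM, N, cc$P_in, cc$C_in, cfg$conv_kernel)
    }
  }
  grads
}

# ---- bidirectional LSTM ----------------------------------------------------

# Fseq: (B*T, C) matrix, row = (b-1)*T + t. Returns hidden states per step.
lstm_forward <- function(prm, Fseq, B, T, H, reverse = FALSE,
                         keep_cache = FALSE) {
  steps <- if (reverse) T:1 else 1:T
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  Hout <- matrix(0, B * T, H)
  cache <- if (keep_cache) vector("list", T) else NULL
  for (s in seq_len(T)) {
    t <- steps[s]
    rows <- (seq_len(B) - 1L) * T + t
    Xt <- Fseq[rows, , drop = FALSE]
    G <- Xt %*% prm$Wx + h %*% prm$Wh
    G <- sweep(G, 2, prm$b, `+`)
    i <- 1 / (1 + exp(-G[, 1:H, drop = FALSE]))
    f <- 1 / (1 + exp(-G[, (H + 1):(2 * H), drop = FALSE]))
    o <- 1 / (1 + exp(-G[, (2 * H + 1):(3 * H), drop = FALSE]))
    g <- tanh(G[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    Hout[rows, ] <- h
    if (keep_cache)
      cache[[s]] <- list(i = i, f = f, o = o, g = g, c = cst, tc = tc,
                         c_prev = c_prev, h_prev = h_prev, rows = rows)
  }
  list(H = Hout, cache = cache, steps = steps)
}

lstm_backward <- function(prm, Fseq, fwd, dH, B, T, H) {
  dWx <- matrix(0, nrow(prm$Wx), ncol(prm$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dF <- matrix(0, nrow(Fseq), ncol(Fseq))
  dh_next <- matrix(0, B, H)
  dc <- matrix(0, B, H)
  for (s in T:1) {
    cc <- fwd$cache[[s]]
    rows <- cc$rows
    dh <- dH[rows, , drop = FALSE] + dh_next
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_prev <- dc * cc$f
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    Xt <- Fseq[rows, , drop = FALSE]
    dWx <- dWx + crossprod(Xt, dG)
    dWh <- dWh + crossprod(cc$h_prev, dG)
    db <- db + colSums(dG)
    dF[rows, ] <- dF[rows, ] + dG %*% t(prm$Wx)
    dh_next <- dG %*% t(prm$Wh)
    dc <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db, dF = dF)
}

# ---- full network ----------------------------------------------------------

# Xm: (N*100, 3) standardized input for N = B*T windows ordered
# sequence-major (window n = (b-1)*T + t). y: integer vector length N,
# 1 = NONSIT, 2 = SIT. Returns loss, per-window probabilities and, when
# want_grads, gradients for every parameter.
nn_loss <- function(params, cfg, Xm, y, B, T, want_grads = FALSE,
                    drop_masks = NULL) {
  N <- B * T
  H <- cfg$rnn_hidden
  cnn <- cnn_forward(params, cfg, Xm, N, keep_cache = want_grads)
  F <- cnn$F
  if (!is.null(drop_masks)) F <- F * drop_masks$F
  lf <- lstm_forward(list(Wx = params$lstmf_Wx, Wh = params$lstmf_Wh,
                          b = params$lstmf_b), F, B, T, H,
                     keep_cache = want_grads)
  lb <- lstm_forward(list(Wx = params$lstmb_Wx, Wh = params$lstmb_Wh,
                          b = params$lstmb_b), F, B, T, H, reverse = TRUE,
                     keep_cache = want_grads)
  Hcat <- cbind(lf$H, lb$H)
  if (!is.null(drop_masks)) Hcat <- Hcat * drop_masks$H
  logits <- sweep(Hcat %*% params$out_W, 2, params$out_b, `+`)
  mx <- pmax(logits[, 1], logits[, 2])
  ez <- exp(logits - mx)
  probs <- ez / rowSums(ez)
  loss <- -mean(log(pmax(probs[cbind(seq_len(N), y)], 1e-12)))
  if (!want_grads) return(list(loss = loss, probs = probs))

  Y <- matrix(0, N, 2); Y[cbind(seq_len(N), y)] <- 1
  dlog <- (probs - Y) / N
  grads <- list(out_W = crossprod(Hcat, dlog), out_b = colSums(dlog))
  dHcat <- dlog %*% t(params$out_W)
  if (!is.null(drop_masks)) dHcat <- dHcat * drop_masks$H
  gf <- lstm_backward(list(Wx = params$lstmf_Wx, Wh = params$lstmf_Wh,
                           b = params$lstmf_b), F, lf,
                      dHcat[, 1:H, drop = FALSE], B, T, H)
  gb <- lstm_backward(list(Wx = params$lstmb_Wx, Wh = params$lstmb_Wh,
                           b = params$lstmb_b), F, lb,
                      dHcat[, (H + 1):(2 * H), drop = FALSE], B, T, H)
  grads$lstmf_Wx <- gf$Wx; grads$lstmf_Wh <- gf$Wh; grads$lstmf_b <- gf$b
  grads$lstmb_Wx <- gb$Wx; grads$lstmb_Wh <- gb$Wh; grads$lstmb_b <- gb$b
  dF <- gf$dF + gb$dF
  if (!is.null(drop_masks)) dF <- dF * drop_masks$F
  grads <- c(grads, cnn_backward(params, cfg, cnn, dF, N))
  list(loss = loss, probs = probs, grads = grads)
}

# ---- initialization and optimizer ------------------------------------------

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

init_params <- function(cfg) {
  # caller is responsible for seeding the RNG
  params <- list()
  cin <- 3L
  k <- cfg$conv_kernel
  for (l in seq_along(cfg$conv_channels)) {
    cout <- cfg$conv_channels[l]
    params[[paste0("conv", l, "_W")]] <- glorot(k * cin, cout)
    params[[paste0("conv", l, "_b")]] <- numeric(cout)
    cin <- cout
  }
  H <- cfg$rnn_hidden
  for (d in c("lstmf", "lstmb")) {
    params[[paste0(d, "_Wx")]] <- glorot(cin, 4 * H)
    params[[paste0(d, "_Wh")]] <- glorot(H, 4 * H)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    params[[paste0(d, "_b")]] <- b
  }
  params$out_W <- glorot(2 * H, 2)
  params$out_b <- numeric(2)
  params
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

n_params <- function(params) sum(vapply(params, length, 0L))

# windows array (100, 3, N) -> (N*100, 3) matrix, window-fastest rows
windows_to_matrix <- function(arr) {
  N <- dim(arr)[3]
  Xm <- matrix(0, N * 100L, 3L)
  for (ch in 1:3) Xm[, ch] <- as.vector(t(arr[, ch, , drop = FALSE][, 1, ]))
  Xm
}
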