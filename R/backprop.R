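# Hand-written backpropagation for the BiLSTM-CRF graph.
#
# The gradient of the negative sequence log-likelihood flows: CRF marginals
# -> emission scores -> fully-connected block -> BiLSTM (backprop through
# time, including the peephole terms) -> concatenated input vector -> the
# embedding tables (and through the character LSTM for the char channel).

# Forward pass over one sentence, keeping everything backprop needs.
sentence_forward <- function(bundle, sentence, vocab, dropout = 0,
                             training = FALSE) {
  fcfg <- bundle$meta$feature_cfg
  emb <- embed_sentence(sentence, bundle$emb, vocab, fcfg, cache = training)
  X <- emb$X
  n <- nrow(X)
  mask_x <- NULL; mask_h <- NULL
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask_x <- matrix(stats::rbinom(length(X), 1, keep) / keep, n, ncol(X))
    X <- X * mask_x
  }
  fwd <- lstm_run(X, bundle$lstm$fwd, cache = training)
  bwd <- lstm_run(X, bundle$lstm$bwd, reverse = TRUE, cache = training)
  H <- cbind(fwd$H, bwd$H)
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask_h <- matrix(stats::rbinom(length(H), 1, keep) / keep, n, ncol(H))
    H <- H * mask_h
  }
  fco <- fc_forward(H, bundle$fc)
  list(emb = emb, X = X, mask_x = mask_x, mask_h = mask_h,
       fwd = fwd, bwd = bwd, H = H, fc = fco, E = fco$E)
}

# Backprop through one LSTM direction.
# X: the (dropped-out) input matrix; run: cached lstm_run; dH: gradient wrt
# the direction's hidden outputs (T x hidden). Returns dX and cell grads.
lstm_backward <- function(X, run, cell, dH) {
  n <- nrow(X)
  hd <- length(cell$b_i)
  peep <- cell_has_peephole(cell)
  g <- zeros_like(cell[!vapply(cell, is.null, TRUE)])
  dX <- matrix(0, n, ncol(X))
  order <- if (run$reverse) rev(seq_len(n)) else seq_len(n)
  dh_carry <- numeric(hd)
  dc_carry <- numeric(hd)
  for (k in rev(seq_along(order))) {
    t <- order[k]
    st <- run$steps[[t]]
    prev <- if (k > 1) run$steps[[order[k - 1]]] else NULL
    h_prev <- if (is.null(prev)) numeric(hd) else prev$h
    c_prev <- if (is.null(prev)) numeric(hd) else prev$c
    dh <- dH[t, ] + dh_carry
    do_ <- dh * st$tanh_c
    dc <- dc_carry + dh * st$o * (1 - st$tanh_c^2)
    da_o <- do_ * st$o * (1 - st$o)
    if (peep) {
      dc <- dc + da_o * cell$w_co
      g$w_co <- g$w_co + da_o * st$c
    }
    df <- dc * c_prev
    di <- dc * st$g
    dg <- dc * st$i
    da_f <- df * st$f * (1 - st$f)
    da_i <- di * st$i * (1 - st$i)
    da_g <- dg * (1 - st$g^2)
    dc_carry <- dc * st$f
    if (peep) {
      dc_carry <- dc_carry + da_i * cell$w_ci + da_f * cell$w_cf
      g$w_ci <- g$w_ci + da_i * c_prev
      g$w_cf <- g$w_cf + da_f * c_prev
    }
    x_t <- X[t, ]
    g$W_xi <- g$W_xi + outer(x_t, da_i)
    g$W_xf <- g$W_xf + outer(x_t, da_f)
    g$W_xc <- g$W_xc + outer(x_t, da_g)
    g$W_xo <- g$W_xo + outer(x_t, da_o)
    g$W_hi <- g$W_hi + outer(h_prev, da_i)
    g$W_hf <- g$W_hf + outer(h_prev, da_f)
    g$W_hc <- g$W_hc + outer(h_prev, da_g)
    g$W_ho <- g$W_ho + outer(h_prev, da_o)
    g$b_i <- g$b_i + da_i
    g$b_f <- g$b_f + da_f
    g$b_c <- g$b_c + da_g
    g$b_o <- g$b_o + da_o
    dh_carry <- drop(cell$W_hi %*% da_i) + drop(cell$W_hf %*% da_f) +
      drop(cell$W_hc %*% da_g) + drop(cell$W_ho %*% da_o)
    dX[t, ] <- drop(cell$W_xi %*% da_i) + drop(cell$W_xf %*% da_f) +
      drop(cell$W_xc %*% da_g) + drop(cell$W_xo %*% da_o)
  }
  list(dX = dX, grads = g)
}

# Loss (negative log-likelihood) and gradients for one sentence.
# gold: integer tag indices. Returns list(loss, grads) with grads shaped like
# the trainable part of the bundle.
sentence_loss_grads <- function(bundle, cache, gold, vocab) {
  E <- cache$E
  n <- nrow(E); L <- ncol(E)
  marg <- crf_marginals(E, bundle$crf)
  score <- crf_path_score(E, gold, bundle$crf)
  loss <- marg$logZ - score
  # d(-ll)/dE = marginal - indicator
  dE <- marg$unary
  dE[cbind(seq_len(n), gold)] <- dE[cbind(seq_len(n), gold)] - 1
  dtrans <- marg$pair
  if (n > 1) {
    for (t in 2:n) {
      dtrans[gold[t - 1], gold[t]] <- dtrans[gold[t - 1], gold[t]] - 1
    }
  }
  dstart <- marg$unary[1, ]; dstart[gold[1]] <- dstart[gold[1]] - 1
  dstop <- marg$unary[n, ]; dstop[gold[n]] <- dstop[gold[n]] - 1

  fc <- bundle$fc
  Y1 <- cache$fc$Y1
  dW2 <- t(Y1) %*% dE
  db2 <- colSums(dE)
  dY1 <- dE %*% t(fc$W2)
  dA1 <- dY1 * (cache$fc$A1 > 0)
  H <- cache$H
  dW1 <- t(H) %*% dA1
  db1 <- colSums(dA1)
  dH <- dA1 %*% t(fc$W1)
  if (!is.null(cache$mask_h)) dH <- dH * cache$mask_h

  hd <- length(bundle$lstm$fwd$b_i)
  bf <- lstm_backward(cache$X, cache$fwd, bundle$lstm$fwd,
                      dH[, seq_len(hd), drop = FALSE])
  bb <- lstm_backward(cache$X, cache$bwd, bundle$lstm$bwd,
                      dH[, hd + seq_len(hd), drop = FALSE])
  dX <- bf$dX + bb$dX
  if (!is.null(cache$mask_x)) dX <- dX * cache$mask_x

  # Embedding gradients
  emb <- cache$emb
  fcfg <- bundle$meta$feature_cfg
  gemb <- zeros_like(unclass(bundle$emb))
  for (row in seq_len(nrow(emb$layout))) {
    ch <- emb$layout$channel[row]
    cols <- emb$layout$start[row]:emb$layout$end[row]
    dXc <- dX[, cols, drop = FALSE]
    if (ch == "char") {
      for (t in seq_len(n)) {
        run <- emb$char_runs[[t]]
        idx <- emb$idx$char[[t]]
        Xc <- bundle$emb$char_table[idx, , drop = FALSE]
        dHc <- matrix(0, length(idx), ncol(dXc))
        dHc[length(idx), ] <- dXc[t, ]
        bc <- lstm_backward(Xc, run, bundle$emb$char_cell, dHc)
        gemb$char_cell <- combine_param_leaves(gemb$char_cell, bc$grads, `+`)
        for (q in seq_along(idx)) {
          gemb$char_table[idx[q], ] <- gemb$char_table[idx[q], ] + bc$dX[q, ]
        }
      }
    } else {
      tab <- switch(ch, word = "word", pos = "pos", entity = "entity", dep = "dep")
      ii <- emb$idx[[ch]]
      for (t in seq_len(n)) {
        gemb[[tab]][ii[t], ] <- gemb[[tab]][ii[t], ] + dXc[t, ]
      }
    }
  }

  list(
    loss = loss,
    grads = list(
      emb = gemb,
      lstm = list(fwd = bf$grads, bwd = bb$grads),
      fc = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
      crf = list(trans = dtrans, start = dstart, stop = dstop)
    )
  )
}
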