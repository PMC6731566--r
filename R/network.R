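# The BiLSTM-CRF computation graph.
#
# LSTM cells follow the peephole formulation: the input and forget gates read
# the previous cell state and the output gate reads the current cell state,
# with the peephole weights acting elementwise (diagonal). A config switch
# turns the peephole terms off for a standard LSTM.
#
# Orientation conventions: token inputs are row vectors; input weights W_x*
# are (input_dim x hidden), recurrent weights W_h* are (hidden x hidden),
# peephole weights w_c* and biases b_* are length-hidden vectors.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize one LSTM cell
#'
#' @param input_dim input vector dimension
#' @param hidden hidden state size
#' @param range uniform initialization half-width
#' @param peephole include peephole weights?
#' @return list of class `lstm_cell` with matrices `W_xi`, `W_xf`, `W_xc`,
#'   `W_xo`, `W_hi`, `W_hf`, `W_hc`, `W_ho`, vectors `w_ci`, `w_cf`, `w_co`
#'   (zero-length when `peephole = FALSE`), and biases `b_i`, `b_f`, `b_c`,
#'   `b_o`
#' @export
init_lstm_cell <- function(input_dim, hidden, range = 0.05, peephole = TRUE) {
  mk <- function(r, c) init_matrix(r, c, range)
  vk <- function(n) stats::runif(n, -range, range)
  cell <- list(
    W_xi = mk(input_dim, hidden), W_xf = mk(input_dim, hidden),
    W_xc = mk(input_dim, hidden), W_xo = mk(input_dim, hidden),
    W_hi = mk(hidden, hidden), W_hf = mk(hidden, hidden),
    W_hc = mk(hidden, hidden), W_ho = mk(hidden, hidden),
    w_ci = if (peephole) vk(hidden) else numeric(0),
    w_cf = if (peephole) vk(hidden) else numeric(0),
    w_co = if (peephole) vk(hidden) else numeric(0),
    b_i = vk(hidden), b_f = vk(hidden), b_c = vk(hidden), b_o = vk(hidden)
  )
  structure(cell, class = "lstm_cell", peephole = peephole, hidden = hidden,
            input_dim = input_dim)
}

cell_has_peephole <- function(cell) length(cell$w_ci) > 0

# Full step keeping gate activations for backpropagation.
lstm_step_full <- function(x, h_prev, c_prev, cell) {
  peep <- cell_has_peephole(cell)
  a_i <- drop(x %*% cell$W_xi) + drop(h_prev %*% cell$W_hi) + cell$b_i
  a_f <- drop(x %*% cell$W_xf) + drop(h_prev %*% cell$W_hf) + cell$b_f
  if (peep) {
    a_i <- a_i + cell$w_ci * c_prev
    a_f <- a_f + cell$w_cf * c_prev
  }
  i <- sigmoid(a_i)
  f <- sigmoid(a_f)
  g <- tanh(drop(x %*% cell$W_xc) + drop(h_prev %*% cell$W_hc) + cell$b_c)
  c_t <- f * c_prev + i * g
  a_o <- drop(x %*% cell$W_xo) + drop(h_prev %*% cell$W_ho) + cell$b_o
  if (peep) a_o <- a_o + cell$w_co * c_t
  o <- sigmoid(a_o)
  tc <- tanh(c_t)
  list(h = o * tc, c = c_t, i = i, f = f, g = g, o = o, tanh_c = tc)
}

#' One LSTM step
#'
#' Applies the gate equations (with peephole terms when the cell has them)
#' to a single input vector: the input and forget gates read the previous
#' cell state, the output gate reads the updated cell state, and
#' `h = o * tanh(c)` — so every hidden component lies in (-1, 1).
#'
#' @param x input vector (length `input_dim`)
#' @param h_prev,c_prev previous hidden / cell state vectors (length `hidden`)
#' @param cell an [init_lstm_cell()] parameter list
#' @return list with `h` and `c`
#' @export
lstm_step <- function(x, h_prev, c_prev, cell) {
  hd <- length(cell$b_i)
  if (length(x) != nrow(cell$W_xi) || length(h_prev) != hd || length(c_prev) != hd) {
    trignet_abort(sprintf(
      "lstm_step: shape mismatch (x %d vs %d, h %d, c %d vs hidden %d)",
      length(x), nrow(cell$W_xi), length(h_prev), length(c_prev), hd))
  }
  st <- lstm_step_full(matrix(x, 1), h_prev, c_prev, cell)
  list(h = st$h, c = st$c)
}

# Run an LSTM over a T x D matrix. Returns H (T x hidden) and, when cached,
# the per-step gate activations needed for backpropagation.
lstm_run <- function(X, cell, reverse = FALSE, cache = FALSE) {
  n <- nrow(X)
  hd <- length(cell$b_i)
  H <- matrix(0, n, hd)
  C <- matrix(0, n, hd)
  steps <- if (cache) vector("list", n) else NULL
  h <- numeric(hd); c <- numeric(hd)
  order <- if (reverse) rev(seq_len(n)) else seq_len(n)
  for (t in order) {
    st <- lstm_step_full(X[t, , drop = FALSE], h, c, cell)
    H[t, ] <- st$h
    C[t, ] <- st$c
    if (cache) steps[[t]] <- st
    h <- st$h; c <- st$c
  }
  list(H = H, C = C, steps = steps, reverse = reverse)
}

#' Bidirectional LSTM over a sentence
#'
#' Concatenates a left-to-right and a right-to-left LSTM pass:
#' `h_t = [h_t_forward; h_t_backward]`, so the forward half of position `t`
#' depends only on positions `<= t` and the backward half only on `>= t`.
#'
#' @param X input matrix, one row per token
#' @param params list with `fwd` and `bwd` [init_lstm_cell()] cells of equal
#'   hidden size
#' @return matrix of dimension `nrow(X)` x `2 * hidden`
#' @export
bilstm_forward <- function(X, params) {
  if (is.null(dim(X)) || nrow(X) == 0) trignet_abort("bilstm_forward: empty sequence")
  f <- lstm_run(X, params$fwd)
  b <- lstm_run(X, params$bwd, reverse = TRUE)
  cbind(f$H, b$H)
}

#' Initialize the fully-connected block
#'
#' A ReLU hidden layer (`y = max(0, W1' h + b1)`, default 600 units) followed
#' by a linear projection to one emission score per tag. The projection is
#' the block the label-overlap partition addresses row-by-row.
#'
#' @param input_dim BiLSTM output dimension (2 x hidden)
#' @param fc_dim hidden layer width
#' @param n_tags size of the tag inventory (trigger labels + negative)
#' @param range uniform initialization half-width
#' @return list with `W1` (`input_dim x fc_dim`), `b1`, `W2`
#'   (`fc_dim x n_tags`), `b2`
#' @export
init_fc <- function(input_dim, fc_dim, n_tags, range = 0.05) {
  list(W1 = init_matrix(input_dim, fc_dim, range),
       b1 = stats::runif(fc_dim, -range, range),
       W2 = init_matrix(fc_dim, n_tags, range),
       b2 = stats::runif(n_tags, -range, range))
}

# Forward through the FC block for a T x 2H matrix of BiLSTM outputs.
fc_forward <- function(H, fc) {
  A1 <- sweep(H %*% fc$W1, 2, fc$b1, `+`)
  Y1 <- pmax(A1, 0)
  E <- sweep(Y1 %*% fc$W2, 2, fc$b2, `+`)
  list(A1 = A1, Y1 = Y1, E = E)
}

#' Emission scores for one BiLSTM output vector
#'
#' ReLU hidden layer then affine projection to per-tag emission scores (no
#' nonlinearity on the scores — the CRF consumes them directly).
#'
#' @param h BiLSTM output vector (or a matrix of them, one per row)
#' @param fc an [init_fc()] parameter list
#' @return numeric vector (or matrix) of emission scores per tag
#' @export
fc_project <- function(h, fc) {
  if (is.null(dim(h))) {
    if (length(h) != nrow(fc$W1)) trignet_abort("fc_project: shape mismatch")
    return(drop(fc_forward(matrix(h, 1), fc)$E))
  }
  if (ncol(h) != nrow(fc$W1)) trignet_abort("fc_project: shape mismatch")
  fc_forward(h, fc)$E
}

# ---------------------------------------------------------------------------
# Linear-chain CRF
# ---------------------------------------------------------------------------

#' Initialize CRF parameters
#'
#' A transition score matrix over the tag inventory plus start/stop score
#' vectors (the two virtual states of the standard linear-chain CRF).
#'
#' @param n_tags tag inventory size
#' @param range uniform initialization half-width (0 gives the uniform model)
#' @return list with `trans` (`n_tags x n_tags`, from-row to-column), `start`,
#'   `stop`
#' @export
init_crf <- function(n_tags, range = 0.05) {
  list(trans = init_matrix(n_tags, n_tags, range),
       start = stats::runif(n_tags, -range, range),
       stop = stats::runif(n_tags, -range, range))
}

crf_check <- function(emissions, crf) {
  if (is.null(dim(emissions)) || nrow(emissions) == 0) {
    trignet_abort("crf: empty emission matrix")
  }
  if (ncol(emissions) != ncol(crf$trans)) {
    trignet_abort("crf: emission columns do not match the tag inventory")
  }
}

# Log-partition via the forward recursion in log space.
crf_log_partition <- function(emissions, crf) {
  crf_check(emissions, crf)
  n <- nrow(emissions); L <- ncol(emissions)
  alpha <- crf$start + emissions[1, ]
  if (n > 1) {
    for (t in 2:n) {
      alpha <- vapply(seq_len(L), function(j) {
        logsumexp(alpha + crf$trans[, j]) + emissions[t, j]
      }, 0)
    }
  }
  logsumexp(alpha + crf$stop)
}

# Score of one tag path (integer indices).
crf_path_score <- function(emissions, tags, crf) {
  n <- nrow(emissions)
  s <- crf$start[tags[1]] + emissions[1, tags[1]]
  if (n > 1) {
    for (t in 2:n) {
      s <- s + crf$trans[tags[t - 1], tags[t]] + emissions[t, tags[t]]
    }
  }
  s + crf$stop[tags[n]]
}

#' CRF sequence log-likelihood
#'
#' `log P(tags | emissions) = score(path) - log Z`, with the partition
#' function from the forward recursion in log space. Always `<= 0`.
#'
#' @param emissions `T x L` emission score matrix
#' @param tags integer tag indices (length `T`) in `1..L`
#' @param crf an [init_crf()] parameter list
#' @return scalar log-likelihood
#' @export
crf_log_likelihood <- function(emissions, tags, crf) {
  crf_check(emissions, crf)
  if (length(tags) != nrow(emissions)) {
    trignet_abort("crf_log_likelihood: |tags| != nrow(emissions)")
  }
  if (any(tags < 1 | tags > ncol(emissions))) {
    trignet_abort("crf_log_likelihood: tag outside the inventory")
  }
  crf_path_score(emissions, tags, crf) - crf_log_partition(emissions, crf)
}

#' Viterbi decoding
#'
#' Most likely tag sequence under the CRF. Ties break toward the lowest tag
#' index, making the decoder deterministic.
#'
#' @inheritParams crf_log_likelihood
#' @return list with integer `tags` and the path `score`
#' @export
crf_viterbi <- function(emissions, crf) {
  crf_check(emissions, crf)
  n <- nrow(emissions); L <- ncol(emissions)
  delta <- crf$start + emissions[1, ]
  back <- matrix(0L, n, L)
  if (n > 1) {
    for (t in 2:n) {
      nd <- numeric(L)
      for (j in seq_len(L)) {
        cand <- delta + crf$trans[, j]
        k <- which.max(cand)  # first maximum = lowest index on ties
        back[t, j] <- k
        nd[j] <- cand[k] + emissions[t, j]
      }
      delta <- nd
    }
  }
  fin <- delta + crf$stop
  tags <- integer(n)
  tags[n] <- which.max(fin)
  if (n > 1) for (t in n:2) tags[t - 1] <- back[t, tags[t]]
  list(tags = tags, score = fin[tags[n]])
}

# Forward-backward marginals; used by the gradient of the negative
# log-likelihood. Returns unary (T x L) and expected transition statistics.
crf_marginals <- function(emissions, crf) {
  n <- nrow(emissions); L <- ncol(emissions)
  alpha <- matrix(0, n, L)
  alpha[1, ] <- crf$start + emissions[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in seq_len(L)) {
        alpha[t, j] <- logsumexp(alpha[t - 1, ] + crf$trans[, j]) + emissions[t, j]
      }
    }
  }
  beta <- matrix(0, n, L)
  beta[n, ] <- crf$stop
  if (n > 1) {
    for (t in (n - 1):1) {
      for (i in seq_len(L)) {
        beta[t, i] <- logsumexp(crf$trans[i, ] + emissions[t + 1, ] + beta[t + 1, ])
      }
    }
  }
  logZ <- logsumexp(alpha[n, ] + crf$stop)
  unary <- exp(alpha + beta - logZ)
  pair <- matrix(0, L, L)
  if (n > 1) {
    for (t in 2:n) {
      lp <- outer(alpha[t - 1, ], rep(1, L)) + crf$trans +
        outer(rep(1, L), emissions[t, ] + beta[t, ])
      pair <- pair + exp(lp - logZ)
    }
  }
  list(unary = unary, pair = pair, logZ = logZ)
}

# ---------------------------------------------------------------------------
# Parameter bundle
# ---------------------------------------------------------------------------

#' Network hyperparameters
#'
#' @param hidden_size LSTM hidden state size per direction (published
#'   default 300)
#' @param fc_dim fully-connected hidden width (published default 600)
#' @param peephole use peephole LSTM cells (the formulation as published)?
#' @param init_range uniform initialization half-width
#' @return object of class `network_config`
#' @export
network_config <- function(hidden_size = 300, fc_dim = 600, peephole = TRUE,
                           init_range = 0.05) {
  structure(list(hidden_size = hidden_size, fc_dim = fc_dim,
                 peephole = peephole, init_range = init_range),
            class = "network_config")
}

#' Initialize a full parameter bundle for one domain
#'
#' All trainable tensors of one network: embedding tables, forward/backward
#' LSTM cells, fully-connected block and CRF, addressable by (layer, block)
#' so sub-blocks can be read and written independently (see
#' [bundle_block_addresses()]).
#'
#' @param vocab the domain vocabulary
#' @param labels the domain [label_set]
#' @param feature_cfg a [feature_config]
#' @param net_cfg a [network_config]
#' @return list of class `parameter_bundle` with elements `emb`, `lstm`
#'   (`fwd`, `bwd`), `fc`, `crf`, and metadata `meta`
#' @export
init_bundle <- function(vocab, labels, feature_cfg, net_cfg = network_config()) {
  D <- total_dim(feature_cfg)
  H <- net_cfg$hidden_size
  tags <- tag_inventory(labels)
  bundle <- list(
    emb = init_embedding_tables(vocab, feature_cfg, net_cfg$init_range),
    lstm = list(
      fwd = init_lstm_cell(D, H, net_cfg$init_range, net_cfg$peephole),
      bwd = init_lstm_cell(D, H, net_cfg$init_range, net_cfg$peephole)
    ),
    fc = init_fc(2 * H, net_cfg$fc_dim, length(tags), net_cfg$init_range),
    crf = init_crf(length(tags), net_cfg$init_range)
  )
  bundle$meta <- list(tags = tags, labels = labels, feature_cfg = feature_cfg,
                      net_cfg = net_cfg)
  class(bundle) <- "parameter_bundle"
  bundle
}

#' Addressable blocks of a parameter bundle
#'
#' Every trainable tensor exactly once, as `layer.block` address strings —
#' the granularity at which transfer plans copy parameters.
#'
#' @param bundle a [init_bundle()] result
#' @return tibble with columns `address` and `n_params`
#' @export
bundle_block_addresses <- function(bundle) {
  rows <- list()
  add <- function(addr, x) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(address = addr,
                                                 n_params = length(x))
  }
  for (nm in names(bundle$emb)) {
    if (nm == "char_cell") {
      for (p in names(bundle$emb$char_cell)) {
        add(paste0("emb.char_cell.", p), bundle$emb$char_cell[[p]])
      }
    } else add(paste0("emb.", nm), bundle$emb[[nm]])
  }
  for (dir in c("fwd", "bwd")) {
    for (p in names(bundle$lstm[[dir]])) {
      add(paste0("lstm.", dir, ".", p), bundle$lstm[[dir]][[p]])
    }
  }
  for (p in names(bundle$fc)) add(paste0("fc.", p), bundle$fc[[p]])
  for (p in names(bundle$crf)) add(paste0("crf.", p), bundle$crf[[p]])
  dplyr::bind_rows(rows)
}

# Number of parameters in a bundle (trainable tensors only).
bundle_n_params <- function(bundle) {
  sum(bundle_block_addresses(bundle)$n_params)
}
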