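# The computation graph: LSTM step, BiLSTM, FC projection, CRF.

test_that("lstm_step implements the peephole gate equations", {
  # zero parameters: gates 0.5, cell and hidden zero
  cell0 <- trignet:::zeros_like(init_lstm_cell(2, 3))
  st <- lstm_step(c(1, -1), rep(0, 3), rep(0, 3), cell0)
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$c, rep(0, 3))

  # scalar cell against an independent step-by-step evaluation
  cell <- list(W_xi = matrix(0.3), W_xf = matrix(-0.2), W_xc = matrix(0.5),
               W_xo = matrix(0.1), W_hi = matrix(0.4), W_hf = matrix(0.2),
               W_hc = matrix(-0.3), W_ho = matrix(0.6),
               w_ci = 0.25, w_cf = -0.15, w_co = 0.35,
               b_i = 0.05, b_f = -0.05, b_c = 0.1, b_o = 0)
  x <- 0.7; h0 <- 0.2; c0 <- -0.4
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(0.3 * x + 0.4 * h0 + 0.25 * c0 + 0.05)
  f <- sig(-0.2 * x + 0.2 * h0 - 0.15 * c0 - 0.05)
  g <- tanh(0.5 * x - 0.3 * h0 + 0.1)
  c1 <- f * c0 + i * g
  o <- sig(0.1 * x + 0.6 * h0 + 0.35 * c1 + 0)
  h1 <- o * tanh(c1)
  st2 <- lstm_step(x, h0, c0, cell)
  expect_equal(st2$c, c1, tolerance = 1e-12)
  expect_equal(st2$h, h1, tolerance = 1e-12)

  # hidden components always in (-1, 1)
  set.seed(5)
  cell_r <- init_lstm_cell(4, 3, range = 2)
  st3 <- lstm_step(stats::rnorm(4), stats::rnorm(3), stats::rnorm(3), cell_r)
  expect_true(all(abs(st3$h) < 1))

  expect_error(lstm_step(c(1, 2, 3), rep(0, 3), rep(0, 3), cell_r))
})

test_that("bilstm halves look left and right respectively", {
  set.seed(6)
  params <- list(fwd = init_lstm_cell(3, 2), bwd = init_lstm_cell(3, 2))
  X <- matrix(stats::rnorm(15), 5, 3)

  H <- bilstm_forward(X, params)
  expect_equal(dim(H), c(5, 4))

  # length-1 sequence: both halves equal a single step from the zero state
  H1 <- bilstm_forward(X[1, , drop = FALSE], params)
  sf <- lstm_step(X[1, ], rep(0, 2), rep(0, 2), params$fwd)
  sb <- lstm_step(X[1, ], rep(0, 2), rep(0, 2), params$bwd)
  expect_equal(drop(H1), c(sf$h, sb$h), tolerance = 1e-12)

  # reversing the input with swapped cells reverses and swaps the halves
  params_sw <- list(fwd = params$bwd, bwd = params$fwd)
  Hr <- bilstm_forward(X[5:1, , drop = FALSE], params_sw)
  expect_equal(Hr[5:1, c(3, 4, 1, 2)], H, tolerance = 1e-12)

  # the forward half at position t must not depend on positions > t
  X2 <- X; X2[5, ] <- X2[5, ] + 1
  H2 <- bilstm_forward(X2, params)
  expect_equal(H2[1:4, 1:2], H[1:4, 1:2], tolerance = 1e-14)
  expect_false(isTRUE(all.equal(H2[1:4, 3:4], H[1:4, 3:4])))

  # zero parameters give zero outputs; empty input errors
  expect_equal(bilstm_forward(X, trignet:::zeros_like(params)),
               matrix(0, 5, 4))
  expect_error(bilstm_forward(X[0, , drop = FALSE], params))
})

test_that("fc projection is relu-then-affine", {
  # identity hidden weights, zero bias: ReLU of the input
  fc <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  expect_equal(fc_project(c(-1, 2), fc), c(0, 2))
  expect_equal(fc_project(c(0, 0), fc), c(0, 0))

  # random parameters match an independently coded evaluation
  set.seed(7)
  fc2 <- init_fc(4, 5, 3, range = 0.5)
  h <- stats::rnorm(4)
  manual <- drop(pmax(h %*% fc2$W1 + fc2$b1, 0) %*% fc2$W2 + fc2$b2)
  expect_equal(fc_project(h, fc2), manual, tolerance = 1e-12)

  expect_error(fc_project(c(1, 2), fc2))
})

test_that("crf log-likelihood and viterbi match exhaustive enumeration", {
  # uniform model: -T log L
  L <- 3; T_ <- 2
  E0 <- matrix(0, T_, L)
  crf0 <- list(trans = matrix(0, L, L), start = rep(0, L), stop = rep(0, L))
  expect_equal(crf_log_likelihood(E0, c(1, 3), crf0), -T_ * log(L),
               tolerance = 1e-12)

  set.seed(8)
  for (case in 1:60) {
    T_ <- sample(1:5, 1)
    L <- sample(2:4, 1)
    E <- matrix(stats::rnorm(T_ * L), T_, L)
    crf <- random_crf(L)
    oracle <- enumerate_crf(E, crf)
    # forward log-partition equals log-sum-exp over all enumerated paths
    expect_equal(trignet:::crf_log_partition(E, crf), oracle$logZ,
                 tolerance = 1e-8)
    # viterbi equals the enumerated maximum
    vit <- crf_viterbi(E, crf)
    expect_equal(vit$score, oracle$best_score, tolerance = 1e-8)
    expect_equal(vit$tags, unname(oracle$best_path))
    # path probabilities sum to one
    probs <- exp(oracle$scores - oracle$logZ)
    expect_equal(sum(probs), 1, tolerance = 1e-8)
    # log-likelihood of a random path is <= 0 and matches enumeration
    p <- sample(L, T_, replace = TRUE)
    ll <- crf_log_likelihood(E, p, crf)
    expect_lte(ll, 1e-12)
  }

  expect_error(crf_log_likelihood(E0, c(1, 5), crf0))
  expect_error(crf_viterbi(matrix(0, 0, 3), crf0))
})

test_that("viterbi ties break toward the lowest tag index", {
  E <- matrix(0, 3, 4)
  crf <- list(trans = matrix(0, 4, 4), start = rep(0, 4), stop = rep(0, 4))
  expect_equal(crf_viterbi(E, crf)$tags, c(1, 1, 1))
})

test_that("zero-parameter network yields uniform crf predictions", {
  pair <- tiny_pair()
  vocab <- build_vocab(pair$target)
  labs <- label_set(c(paste0("S", 1:2), paste0("T", 1:3)))
  set.seed(10)
  bundle <- init_bundle(vocab, labs, small_feature_cfg(), small_net_cfg())
  zb <- bundle
  zb[c("emb", "lstm", "fc", "crf")] <-
    trignet:::zeros_like(trignet:::trainable_part(bundle))
  s <- trignet:::corpus_sentences(pair$target)[[1]]
  cache <- trignet:::sentence_forward(zb, s, vocab)
  expect_equal(cache$E, matrix(0, nrow(s), n_tags(labs)))
  ll <- crf_log_likelihood(cache$E, rep(1, nrow(s)), zb$crf)
  expect_equal(ll, -nrow(s) * log(n_tags(labs)), tolerance = 1e-10)
})

test_that("backpropagation matches numerical gradients", {
  pair <- tiny_pair()
  corpus <- pair$target
  fcfg <- small_feature_cfg(channels = c("word", "char", "pos", "entity", "dep"))
  ncfg <- small_net_cfg(hidden = 4)
  vocab <- build_vocab(corpus)
  labs <- label_set(c(paste0("S", 1:2), paste0("T", 1:3)))
  set.seed(11)
  bundle <- init_bundle(vocab, labs, fcfg, ncfg)
  s <- trignet:::corpus_sentences(corpus)[[1]]
  gold <- match(s$tag, bundle$meta$tags)
  loss_at <- function(b) {
    cache <- trignet:::sentence_forward(b, s, vocab)
    m <- trignet:::crf_marginals(cache$E, b$crf)
    m$logZ - trignet:::crf_path_score(cache$E, gold, b$crf)
  }
  cache <- trignet:::sentence_forward(bundle, s, vocab, training = TRUE)
  sg <- trignet:::sentence_loss_grads(bundle, cache, gold, vocab)
  eps <- 1e-6
  spots <- list(
    c("lstm", "fwd", "W_xi"), c("lstm", "bwd", "W_hc"), c("lstm", "fwd", "w_co"),
    c("fc", "W1"), c("fc", "W2"), c("crf", "trans"),
    c("emb", "word"), c("emb", "char_table"), c("emb", "char_cell", "W_hf")
  )
  set.seed(12)
  for (path in spots) {
    tensor <- bundle[[path]]
    gmat <- sg$grads[[path]]
    for (i in sample(length(tensor), min(3, length(tensor)))) {
      bp <- bundle; bp[[path]][i] <- bp[[path]][i] + eps
      bm <- bundle; bm[[path]][i] <- bm[[path]][i] - eps
      num <- (loss_at(bp) - loss_at(bm)) / (2 * eps)
      expect_lt(abs(gmat[i] - num), 1e-6)
    }
  }
})
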