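# Training: Adam / SGD on the negative CRF log-likelihood, inverted dropout
# before the BiLSTM and fully-connected layers, global-norm gradient
# clipping, and early stopping on development-set micro F1.

#' Training configuration
#'
#' @param epochs maximum training epochs
#' @param batch_size sentences per update (gradients are averaged)
#' @param lr learning rate
#' @param optimizer `"adam"` or `"sgd"` (plain full-gradient descent; useful
#'   for descent checks)
#' @param dropout dropout probability applied before the BiLSTM and
#'   fully-connected layers during training (published value 0.5)
#' @param clip global gradient-norm clipping threshold (`Inf` disables)
#' @param patience early-stopping patience in epochs (used when a dev corpus
#'   is supplied)
#' @param seed integer seed controlling initialization, shuffling and dropout
#' @param source_ratio fraction of source-domain documents used in phase-1
#'   transfer training
#' @param phase1_epochs epochs for the source phase (defaults to `epochs`)
#' @param phase3_lr fine-tuning learning rate for the target phase of
#'   transfer training (defaults to `lr`); a smaller rate protects
#'   transferred parameters from being overwritten early in phase 3
#' @param source_dev_frac fraction of source documents held out as a source
#'   dev split for phase-1 early stopping (0 disables)
#' @param min_count vocabulary minimum frequency
#' @return object of class `train_config`
#' @export
train_config <- function(epochs = 30, batch_size = 16, lr = 1e-3,
                         optimizer = c("adam", "sgd"), dropout = 0.5,
                         clip = 5, patience = 5, seed = 1L,
                         source_ratio = 1, phase1_epochs = NULL,
                         phase3_lr = NULL, source_dev_frac = 0.1,
                         min_count = 1L) {
  optimizer <- match.arg(optimizer)
  if (source_ratio < 0 || source_ratio > 1) {
    trignet_abort("source_ratio must lie in [0, 1]")
  }
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 optimizer = optimizer, dropout = dropout, clip = clip,
                 patience = patience, seed = as.integer(seed),
                 source_ratio = source_ratio,
                 phase1_epochs = phase1_epochs %||% epochs,
                 phase3_lr = phase3_lr,
                 source_dev_frac = source_dev_frac,
                 min_count = min_count),
            class = "train_config")
}

trainable_part <- function(bundle) bundle[c("emb", "lstm", "fc", "crf")]

grad_global_norm <- function(grads) {
  sqrt(reduce_param_leaves(grads, function(acc, leaf) acc + sum(leaf^2), 0))
}

scale_grads <- function(grads, s) {
  map_param_leaves(grads, function(leaf, path) leaf * s)
}

zero_frozen <- function(grads, frozen) {
  if (!length(frozen)) return(grads)
  map_param_leaves(grads, function(leaf, path) {
    if (length(path) >= 2 && path[1] == "emb" && path[2] %in% frozen) leaf * 0 else leaf
  })
}

# Zero the gradients of every block a freeze plan covers (optional phase-3
# freeze of transferred parameters).
zero_plan_blocks <- function(grads, plan, bundle) {
  layout <- channel_layout(bundle$meta$feature_cfg)
  tags <- bundle$meta$tags
  for (k in seq_len(nrow(plan$entries))) {
    e <- plan$entries[k, ]
    if (e$layer == "emb" && e$block == "table") {
      if (e$detail == "char") {
        grads$emb$char_table[] <- 0
        grads$emb$char_cell <- zeros_like(grads$emb$char_cell)
      } else grads$emb[[e$detail]][] <- 0
    } else if (e$layer == "lstm" && e$block %in% c("recurrent", "peephole", "bias")) {
      pars <- switch(e$block,
                     recurrent = c("W_hi", "W_hf", "W_hc", "W_ho"),
                     peephole = c("w_ci", "w_cf", "w_co"),
                     bias = c("b_i", "b_f", "b_c", "b_o"))
      for (dir in c("fwd", "bwd")) for (p in pars) grads$lstm[[dir]][[p]][] <- 0
    } else if (e$layer == "lstm" && e$block == "input") {
      row <- layout[layout$channel == e$detail, ]
      for (dir in c("fwd", "bwd")) {
        for (p in c("W_xi", "W_xf", "W_xc", "W_xo")) {
          grads$lstm[[dir]][[p]][row$start:row$end, ] <- 0
        }
      }
    } else if (e$layer == "fc" && e$block == "hidden") {
      grads$fc$W1[] <- 0; grads$fc$b1[] <- 0
    } else if (e$layer == "fc" && e$block == "label") {
      j <- match(e$detail, tags)
      grads$fc$W2[, j] <- 0; grads$fc$b2[j] <- 0
    } else if (e$layer == "fc" && e$block == "negative") {
      j <- match(bundle$meta$labels$negative, tags)
      grads$fc$W2[, j] <- 0; grads$fc$b2[j] <- 0
    } else if (e$layer == "crf" && e$block == "shared_transitions") {
      sh <- plan$overlap$shared
      j <- match(sh, tags)
      grads$crf$trans[j, j] <- 0
      grads$crf$start[j] <- 0; grads$crf$stop[j] <- 0
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- combine_param_leaves(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- combine_param_leaves(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- combine_param_leaves(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- combine_param_leaves(params, step, `-`)
  list(params = params, state = state)
}

corpus_to_examples <- function(corpus, tags) {
  sents <- corpus_sentences(corpus)
  lapply(sents, function(s) {
    gold <- match(s$tag, tags)
    if (anyNA(gold)) {
      trignet_abort(sprintf("tag(s) outside the label set: %s",
                            paste(unique(s$tag[is.na(gold)]), collapse = ", ")))
    }
    list(sentence = s, gold = gold)
  })
}

# Core fit loop used by both plain and transfer training. `after_init` is a
# hook applied to the freshly initialized bundle (e.g. a parameter transfer);
# it must not consume RNG draws, which keeps no-transfer runs bit-identical
# to train_basic at the same seed.
fit_domain <- function(corpus, labels, feature_cfg,
                       net_cfg = network_config(), config = train_config(),
                       dev = NULL, after_init = NULL, pretrained = NULL,
                       vocab_corpus = NULL) {
  if (nrow(corpus) == 0) trignet_abort("training corpus is empty")
  set.seed(config$seed)
  vocab <- build_vocab(dplyr::bind_rows(corpus, vocab_corpus),
                       min_count = config$min_count)
  bundle <- init_bundle(vocab, labels, feature_cfg, net_cfg)
  if (!is.null(pretrained)) {
    for (ch in names(pretrained)) {
      res <- apply_pretrained(bundle$emb, vocab, pretrained[[ch]], channel = ch)
      bundle$emb <- res$tables
    }
  }
  if (!is.null(after_init)) bundle <- after_init(bundle, vocab)
  tags <- bundle$meta$tags
  examples <- corpus_to_examples(corpus, tags)
  n <- length(examples)
  frozen <- attr(bundle$emb, "frozen") %||% character()
  freeze_plan <- attr(bundle, "freeze_plan")

  params <- trainable_part(bundle)
  state <- if (config$optimizer == "adam") adam_init(params) else NULL
  history <- list()
  best <- list(f1 = -Inf, params = params, epoch = 0L)
  bad_epochs <- 0L

  # Score the initial parameters too, so a transferred initialization can be
  # kept when no training epoch improves on it.
  if (!is.null(dev) && nrow(dev) > 0 && !is.null(after_init)) {
    model0 <- new_trignet_model(bundle, vocab, labels, feature_cfg, net_cfg,
                                config, history = NULL)
    best <- list(f1 = micro_f1(dev, predict_tags(model0, dev), labels),
                 params = params, epoch = 0L)
  }

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    b0 <- 1L
    while (b0 <= n) {
      idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
      b0 <- b0 + config$batch_size
      acc <- NULL
      bundle[c("emb", "lstm", "fc", "crf")] <- params
      for (i in idx) {
        ex <- examples[[i]]
        cache <- sentence_forward(bundle, ex$sentence, vocab,
                                  dropout = config$dropout, training = TRUE)
        sg <- sentence_loss_grads(bundle, cache, ex$gold, vocab)
        epoch_loss <- epoch_loss + sg$loss
        acc <- if (is.null(acc)) sg$grads else combine_param_leaves(acc, sg$grads, `+`)
      }
      grads <- scale_grads(acc, 1 / length(idx))
      grads <- zero_frozen(grads, frozen)
      if (!is.null(freeze_plan)) grads <- zero_plan_blocks(grads, freeze_plan, bundle)
      gn <- grad_global_norm(grads)
      if (is.finite(config$clip) && gn > config$clip) {
        grads <- scale_grads(grads, config$clip / gn)
      }
      if (config$optimizer == "adam") {
        upd <- adam_update(params, grads, state, config$lr)
        params <- upd$params
        state <- upd$state
      } else {
        params <- combine_param_leaves(params, scale_grads(grads, config$lr), `-`)
      }
    }
    bundle[c("emb", "lstm", "fc", "crf")] <- params
    dev_f1 <- NA_real_
    if (!is.null(dev) && nrow(dev) > 0) {
      model_now <- new_trignet_model(bundle, vocab, labels, feature_cfg,
                                     net_cfg, config, history = NULL)
      dev_f1 <- micro_f1(dev, predict_tags(model_now, dev), labels)
      if (dev_f1 > best$f1) {
        best <- list(f1 = dev_f1, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = epoch_loss / n,
                                       dev_f1 = dev_f1)
    if (!is.null(dev) && bad_epochs >= config$patience) break
  }

  if (!is.null(dev) && is.finite(best$f1)) {
    params <- best$params
    bundle[c("emb", "lstm", "fc", "crf")] <- params
  }
  new_trignet_model(bundle, vocab, labels, feature_cfg, net_cfg, config,
                    history = dplyr::bind_rows(history),
                    best_epoch = if (is.null(dev)) NA_integer_ else best$epoch)
}

new_trignet_model <- function(bundle, vocab, labels, feature_cfg, net_cfg,
                              train_cfg, history = NULL, best_epoch = NA_integer_) {
  structure(list(bundle = bundle, vocab = vocab, labels = labels,
                 feature_cfg = feature_cfg, net_cfg = net_cfg,
                 train_cfg = train_cfg, history = history,
                 best_epoch = best_epoch),
            class = "trignet_model")
}

#' Train the basic BiLSTM-CRF tagger on one domain
#'
#' The baseline single-domain model: embedding layer, BiLSTM with peephole
#' cells, ReLU fully-connected layer, and a linear-chain CRF trained by
#' maximizing the sequence log-likelihood. Fully seeded: the same seed and
#' data give bit-identical parameter trajectories.
#'
#' @param corpus training corpus tibble
#' @param labels the domain [label_set]
#' @param feature_cfg a [feature_config]
#' @param net_cfg a [network_config]
#' @param config a [train_config]
#' @param dev optional development corpus for early stopping on micro F1
#' @param pretrained optional named list of pre-trained tables
#'   (`word` and/or `dep`) from [load_word2vec_text()]
#' @return object of class `trignet_model`
#' @export
train_basic <- function(corpus, labels, feature_cfg,
                        net_cfg = network_config(), config = train_config(),
                        dev = NULL, pretrained = NULL) {
  fit_domain(corpus, labels, feature_cfg, net_cfg, config, dev = dev,
             pretrained = pretrained)
}

#' Predict trigger tags for a corpus
#'
#' Viterbi decoding with dropout disabled — deterministic given parameters.
#'
#' @param model a [train_basic()] / [three_phase_train()] model
#' @param corpus corpus tibble to tag
#' @return the corpus with a `.pred` column of predicted tags
#' @export
predict_tags <- function(model, corpus) {
  tags <- model$bundle$meta$tags
  sents <- corpus_sentences(corpus)
  preds <- character(nrow(corpus))
  at <- 1L
  for (s in sents) {
    cache <- sentence_forward(model$bundle, s, model$vocab, dropout = 0,
                              training = FALSE)
    vit <- crf_viterbi(cache$E, model$bundle$crf)
    preds[at:(at + nrow(s) - 1L)] <- tags[vit$tags]
    at <- at + nrow(s)
  }
  corpus$.pred <- preds
  corpus
}

#' @export
predict.trignet_model <- function(object, newdata, ...) {
  predict_tags(object, newdata)
}

#' @export
print.trignet_model <- function(x, ...) {
  cat("<trignet_model> ", length(x$labels$labels), " trigger types, ",
      bundle_n_params(x$bundle), " parameters\n", sep = "")
  if (!is.null(x$history) && nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat("  epochs:", last$epoch)
    if (!is.na(last$dev_f1)) cat("  dev F1:", round_half_up(last$dev_f1), "")
    cat("\n")
  }
  invisible(x)
}

# Micro F1 (percent) of predictions against gold, negative tag excluded.
micro_f1 <- function(gold_corpus, pred_corpus, labels) {
  counts <- count_confusion(gold_corpus$tag, pred_corpus$.pred, labels)
  m <- compute_metrics(counts)
  m$f1[m$type == "TOTAL"]
}
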