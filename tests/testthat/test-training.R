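# Training behaviour: determinism, descent, separable-data sanity, and the
# no-transfer equivalence of the three-phase procedure.

train_labels <- label_set(paste0("S", 1:3))

sep_corpus <- function(n_docs, seed, ambiguity = 0) {
  cfg <- synth_config(source_labels = paste0("S", 1:3),
                      target_labels = paste0("S", 1:3),
                      source_docs = 0, target_docs = n_docs,
                      sentences_per_doc = 5, ambiguity = ambiguity,
                      seed = seed)
  generate_domain_pair(cfg)$target
}

fast_cfg <- function(...) {
  train_config(batch_size = 4, lr = 0.02, dropout = 0, patience = 99,
               min_count = 1, ...)
}

test_that("training is bit-for-bit reproducible at a fixed seed", {
  corp <- sep_corpus(4, seed = 21)
  fcfg <- small_feature_cfg()
  ncfg <- small_net_cfg()
  cfg <- train_config(epochs = 3, batch_size = 4, lr = 0.01, dropout = 0.3,
                      seed = 99)
  m1 <- train_basic(corp, train_labels, fcfg, ncfg, cfg)
  m2 <- train_basic(corp, train_labels, fcfg, ncfg, cfg)
  expect_identical(m1$bundle[c("emb", "lstm", "fc", "crf")],
                   m2$bundle[c("emb", "lstm", "fc", "crf")])
  expect_identical(m1$history, m2$history)

  # a different seed moves the parameters
  cfg2 <- cfg; cfg2$seed <- 100L
  m3 <- train_basic(corp, train_labels, fcfg, ncfg, cfg2)
  expect_false(identical(m1$bundle$fc$W2, m3$bundle$fc$W2))

  # inference is deterministic (dropout off at prediction time)
  p1 <- predict_tags(m1, corp)
  p2 <- predict_tags(m1, corp)
  expect_identical(p1$.pred, p2$.pred)

  expect_error(train_basic(read_conll(character()), train_labels, fcfg, ncfg, cfg))
})

test_that("full-batch gradient descent decreases the loss", {
  corp <- sep_corpus(2, seed = 22) # 10 sentences
  cfg <- train_config(epochs = 8, batch_size = 1000, lr = 0.05,
                      optimizer = "sgd", dropout = 0, clip = Inf, seed = 1)
  m <- train_basic(corp, train_labels, small_feature_cfg(), small_net_cfg(), cfg)
  expect_true(all(diff(m$history$loss) <= 1e-8))
})

test_that("an unambiguous lexicon is learned to training F1 100 within 30 epochs", {
  corp <- sep_corpus(10, seed = 23, ambiguity = 0) # 50 sentences
  fcfg <- feature_config(dim_word = 12, dim_pos = 3, dim_entity = 3,
                         dim_dep = 6, channels = c("word", "pos", "entity", "dep"))
  # tiny-regime optimization: a wide init and a hot learning rate are what
  # break the label-exchange symmetry quickly on a 50-sentence corpus
  m <- train_basic(corp, train_labels, fcfg,
                   network_config(hidden_size = 8, fc_dim = 8, init_range = 0.5),
                   train_config(epochs = 30, batch_size = 4, lr = 0.05,
                                dropout = 0, patience = 99, seed = 2))
  f1 <- trignet:::micro_f1(corp, predict_tags(m, corp), train_labels)
  expect_equal(f1, 100)
})

test_that("no-transfer three-phase training reproduces train_basic bit for bit", {
  pair <- tiny_pair(seed = 31, source_docs = 3, target_docs = 4)
  t_labels <- label_set(c(paste0("S", 1:2), paste0("T", 1:3)))
  s_spec <- domain_spec("s", label_set(paste0("S", 1:4)), small_feature_cfg(4))
  t_spec <- domain_spec("t", t_labels, small_feature_cfg(8))
  plan <- build_transfer_plan(s_spec, t_spec, variant = "A")
  cfg <- train_config(epochs = 3, batch_size = 4, lr = 0.01, dropout = 0.2,
                      seed = 7, source_ratio = 0)
  fit <- three_phase_train(pair$source, pair$target, NULL, plan,
                           small_net_cfg(), cfg)
  base <- train_basic(pair$target, t_labels, t_spec$feature_cfg,
                      small_net_cfg(), cfg)
  expect_identical(fit$model$bundle[c("emb", "lstm", "fc", "crf")],
                   base$bundle[c("emb", "lstm", "fc", "crf")])
  expect_null(fit$source_model)
})

test_that("identity transfer with a frozen phase 3 preserves the source model", {
  corp <- sep_corpus(6, seed = 24)
  parts <- split_corpus(corp, c(train = 5, dev = 1))
  spec <- domain_spec("d", train_labels, small_feature_cfg(),
                      domain_dependent = character())
  m_src <- train_basic(parts$train, train_labels, spec$feature_cfg,
                       small_net_cfg(), fast_cfg(epochs = 6, seed = 3))
  plan <- build_transfer_plan(spec, spec, variant = "D", share_crf = TRUE)
  cfg <- fast_cfg(epochs = 2, seed = 3, source_dev_frac = 0)
  fit <- three_phase_train(parts$train, parts$train, parts$dev, plan,
                           small_net_cfg(), cfg, freeze_shared = TRUE)
  # every shared block is frozen in phase 3, so the target model scores
  # exactly like a fresh source-side fit on the same data
  src_rep <- evaluate_model(fit$source_model, parts$dev)
  tgt_rep <- evaluate_model(fit$model, parts$dev)
  expect_equal(tgt_rep$f1, src_rep$f1)
})

test_that("ratio sweep has one row per ratio and degenerates to the baseline", {
  pair <- tiny_pair(seed = 41, source_docs = 4, target_docs = 5)
  t_labels <- label_set(c(paste0("S", 1:2), paste0("T", 1:3)))
  s_spec <- domain_spec("s", label_set(paste0("S", 1:4)), small_feature_cfg(4))
  t_spec <- domain_spec("t", t_labels, small_feature_cfg(8))
  plan <- build_transfer_plan(s_spec, t_spec, variant = "D")
  parts <- split_corpus(pair$target, c(train = 3, dev = 2))
  cfg <- fast_cfg(epochs = 2, seed = 1, phase1_epochs = 2)
  sweep <- run_ratio_sweep(pair$source, parts$train, parts$dev, plan,
                           ratios = c(0, 0.5), seeds = c(1, 2),
                           net_cfg = small_net_cfg(), config = cfg)
  expect_equal(nrow(sweep), 2)
  expect_equal(sweep$n_seeds, c(2L, 2L))
  runs <- attr(sweep, "runs")
  expect_equal(nrow(runs), 4)
  expect_s3_class(autoplot(sweep), "ggplot")

  # ratio 0 collapses to the no-transfer baseline (dev-selected, like the sweep)
  base_f1 <- vapply(c(1, 2), function(s) {
    m <- train_basic(parts$train, t_labels, t_spec$feature_cfg, small_net_cfg(),
                     fast_cfg(epochs = 2, seed = s), dev = parts$dev)
    trignet:::micro_f1(parts$dev, predict_tags(m, parts$dev), t_labels)
  }, 0)
  expect_equal(sweep$mean_f1[sweep$ratio == 0], mean(base_f1))
})

test_that("tidiers and plots summarise fitted models", {
  corp <- sep_corpus(3, seed = 25)
  m <- train_basic(corp, train_labels, small_feature_cfg(), small_net_cfg(),
                   fast_cfg(epochs = 2, seed = 1))
  td <- tidy(m)
  expect_true(all(c("layer", "block", "n_params") %in% names(td)))
  expect_equal(sum(td$n_params), trignet:::bundle_n_params(m$bundle))
  gl <- glance(m)
  expect_equal(gl$epochs, 2)
  expect_s3_class(autoplot(m), "ggplot")
  rep <- evaluate_model(m, corp)
  expect_s3_class(autoplot(rep), "ggplot")
})
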