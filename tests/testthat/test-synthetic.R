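# The synthetic domain-pair generator: determinism, ledger bookkeeping,
# invertibility, and the overlap/size geometry of the fixture suite.

test_that("generation is seed-deterministic and zero sizes give empty output", {
  cfg <- synth_config(source_labels = "A", target_labels = c("A", "B"),
                      source_docs = 0, target_docs = 0, seed = 1)
  pair <- generate_domain_pair(cfg)
  expect_equal(nrow(pair$source), 0)
  expect_equal(nrow(pair$target), 0)
  expect_equal(sum(pair$ledger$target_counts$n), 0)

  p1 <- tiny_pair(seed = 33)
  p2 <- tiny_pair(seed = 33)
  expect_identical(p1$source, p2$source)
  expect_identical(p1$target, p2$target)
  p3 <- tiny_pair(seed = 34)
  expect_false(identical(p1$target, p3$target))
})

test_that("emitted label sets and lexicon sharing follow the configuration", {
  pair <- tiny_pair()
  src_emitted <- setdiff(unique(pair$source$tag), "O")
  tgt_emitted <- setdiff(unique(pair$target$tag), "O")
  expect_true(all(src_emitted %in% paste0("S", 1:4)))
  expect_true(all(tgt_emitted %in% c(paste0("S", 1:2), paste0("T", 1:3))))
  # overlap of emitted sets is inside the configured intersection
  expect_true(all(intersect(src_emitted, tgt_emitted) %in% paste0("S", 1:2)))

  # shared labels draw from one lexicon: the same trigger words appear for a
  # shared label in both domains
  lex <- pair$ledger$lexicon
  shared_words <- lex$word[lex$label %in% paste0("S", 1:2) & !lex$ambiguous]
  src_words <- pair$source$token[pair$source$tag %in% paste0("S", 1:2)]
  tgt_words <- pair$target$token[pair$target$tag %in% paste0("S", 1:2)]
  expect_true(all(setdiff(src_words, lex$word[lex$ambiguous]) %in% shared_words))
  expect_true(all(setdiff(tgt_words, lex$word[lex$ambiguous]) %in% shared_words))
})

test_that("ledger counts equal corpus statistics exactly", {
  pair <- tiny_pair(seed = 5, source_docs = 8, target_docs = 6)
  for (side in c("source", "target")) {
    st <- corpus_stats(pair[[side]])
    led <- pair$ledger[[paste0(side, "_counts")]]
    expect_equal(sum(led$n), st$triggers)
    m <- merge(led, st$per_type, by.x = "label", by.y = "type", all.x = TRUE)
    m$n.y[is.na(m$n.y)] <- 0L
    expect_equal(m$n.x, m$n.y)
  }
})

test_that("per-label frequencies match the configured rate", {
  labs <- paste0("L", 1:4)
  cfg <- synth_config(source_labels = labs, target_labels = labs,
                      source_docs = 0, target_docs = 400,
                      sentences_per_doc = 5, trigger_rate = 1.2,
                      ambiguity = 0, seed = 77)
  pair <- generate_domain_pair(cfg)
  n_sent <- corpus_stats(pair$target)$sentences
  # each sentence draws Binomial(2, rate/2) triggers, labels ~ uniform;
  # allow three standard errors around the expectation
  expected <- n_sent * cfg$trigger_rate / length(labs)
  se <- sqrt(n_sent * cfg$trigger_rate / length(labs))
  for (l in labs) {
    n <- pair$ledger$target_counts$n[pair$ledger$target_counts$label == l]
    expect_lt(abs(n - expected), 3.5 * se)
  }
})

test_that("the generator is invertible through oracle_tag", {
  pair <- tiny_pair(seed = 11, source_docs = 6, target_docs = 6)
  for (s in trignet:::corpus_sentences(pair$target)) {
    expect_identical(oracle_tag(s, pair$ledger), s$tag)
  }
  for (s in trignet:::corpus_sentences(pair$source)) {
    expect_identical(oracle_tag(s, pair$ledger), s$tag)
  }
})

test_that("lexicon lookup alone resolves nothing ambiguous, everything else", {
  # ambiguity 0: a pure lexicon lookup reaches F1 = 100
  labs <- paste0("L", 1:3)
  cfg0 <- synth_config(source_labels = labs, target_labels = labs,
                       source_docs = 0, target_docs = 20, ambiguity = 0,
                       seed = 13)
  pair0 <- generate_domain_pair(cfg0)
  lex <- pair0$ledger$lexicon
  lookup <- stats::setNames(lex$label, lex$word)
  pred <- unname(lookup[pair0$target$token])
  pred[is.na(pred)] <- "O"
  m <- compute_metrics(count_confusion(pair0$target$tag, pred, label_set(labs)))
  expect_equal(m$f1[m$type == "TOTAL"], 100)

  # ambiguity 1: the same lookup must fall short (context carries the label)
  cfg1 <- synth_config(source_labels = labs, target_labels = labs,
                       source_docs = 0, target_docs = 40, ambiguity = 1,
                       seed = 13)
  pair1 <- generate_domain_pair(cfg1)
  lex1 <- pair1$ledger$lexicon
  lookup1 <- stats::setNames(lex1$label, lex1$word)
  pred1 <- unname(lookup1[pair1$target$token])
  pred1[is.na(pred1)] <- "O"
  m1 <- compute_metrics(count_confusion(pair1$target$tag, pred1, label_set(labs)))
  expect_lt(m1$f1[m1$type == "TOTAL"], 100)
})

test_that("the generated testbed is learnable by the basic tagger", {
  # 500 training sentences at ambiguity 0.3: the single-domain model should
  # come close to the oracle ceiling, establishing the testbed on which
  # transfer gains are measured
  bench <- learnability_benchmark(seed = 1)
  expect_gte(bench$dev_f1, 90)
})

test_that("the fixture suite reproduces the published geometry", {
  dir <- withr::local_tempdir()
  fix <- make_fixture_suite(dir, seed = 42)
  cfg <- fix$config
  # 9-label source nested in a 19-label target
  ov <- compute_label_overlap(label_set(cfg$source_labels),
                              label_set(cfg$target_labels))
  expect_length(ov$shared, 9)
  expect_length(ov$source_only, 0)
  # source/target document ratio 3.6 within a tenth
  ratio <- cfg$source_docs / cfg$target_docs
  expect_lt(abs(ratio - 3.6), 0.1 + 1e-9)
  expect_true(file.exists(file.path(dir, "source.conll")))

  # regeneration with the stored seed is byte-identical
  dir2 <- withr::local_tempdir()
  make_fixture_suite(dir2, seed = 42)
  expect_identical(readLines(file.path(dir, "target.conll")),
                   readLines(file.path(dir2, "target.conll")))

  # generator output round-trips through the column dialect
  back <- read_conll(file.path(dir, "target.conll"))
  expect_equal(as.data.frame(back),
               as.data.frame(fix$pair$target[, trignet:::corpus_columns]))
})
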