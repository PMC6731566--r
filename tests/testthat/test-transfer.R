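# Transfer plans, parameter copying, partitioned layers, subsampling.

src_spec <- function(entity_dim = 4) {
  domain_spec("src", st09_label_set(), small_feature_cfg(dim_entity = entity_dim))
}
tgt_spec <- function(entity_dim = 8) {
  domain_spec("tgt", mlee_label_set(), small_feature_cfg(dim_entity = entity_dim))
}
# identical feature sets, no domain-dependent channels
flat_spec <- function(name, labels) {
  domain_spec(name, labels, small_feature_cfg(), domain_dependent = character())
}

test_that("plan variants share the blocks they should", {
  # generalized plan over the published geometry: 9 shared projection rows,
  # entity input rows unshared, all other BiLSTM blocks shared
  plan <- build_transfer_plan(src_spec(), tgt_spec(), variant = "D")
  lab_rows <- plan$entries[plan$entries$block == "label", ]
  expect_equal(nrow(lab_rows), 9)
  expect_setequal(lab_rows$detail,
                  compute_label_overlap(st09_label_set(), mlee_label_set())$shared)
  input_rows <- plan$entries[plan$entries$block == "input", ]
  expect_false("entity" %in% input_rows$detail)
  expect_setequal(input_rows$detail, c("word", "pos", "dep"))
  expect_true(all(c("recurrent", "peephole", "bias") %in% plan$entries$block))
  expect_true("hidden" %in% plan$entries$block)
  # CRF blocks are never shared
  expect_false("crf" %in% plan$entries$layer)

  # embedding-only variant shares exactly the domain-independent tables
  planC <- build_transfer_plan(src_spec(), tgt_spec(), variant = "C")
  expect_setequal(planC$entries$detail, c("word", "pos", "dep"))
  expect_true(all(planC$entries$layer == "emb"))

  # the no-transfer variant is empty
  planA <- build_transfer_plan(src_spec(), tgt_spec(), variant = "A")
  expect_equal(nrow(planA$entries), 0)

  # B requires feature consistency
  expect_error(build_transfer_plan(src_spec(), tgt_spec(), variant = "B"))
})

test_that("plan-reduction laws hold exactly", {
  dis_src <- flat_spec("s", label_set(c("A", "B")))
  dis_tgt <- flat_spec("t", label_set(c("C", "D", "E")))

  # identical features + disjoint labels: D collapses to B
  planB <- build_transfer_plan(dis_src, dis_tgt, variant = "B")
  planD <- build_transfer_plan(dis_src, dis_tgt, variant = "D")
  expect_true(plan_equal(planD, planB))
  expect_false(any(planD$entries$layer == "fc"))

  # inconsistent features + disjoint labels: D collapses to C
  dis_src2 <- domain_spec("s", label_set(c("A", "B")), small_feature_cfg(dim_entity = 4))
  dis_tgt2 <- domain_spec("t", label_set(c("C", "D")), small_feature_cfg(dim_entity = 8))
  planC2 <- build_transfer_plan(dis_src2, dis_tgt2, variant = "C")
  planD2 <- build_transfer_plan(dis_src2, dis_tgt2, variant = "D")
  expect_true(plan_equal(planD2, planC2))
})

test_that("transfer copies exactly the planned blocks and is idempotent", {
  pair <- tiny_pair()
  s_labels <- label_set(paste0("S", 1:4))
  t_labels <- label_set(c(paste0("S", 1:2), paste0("T", 1:3)))
  s_spec <- domain_spec("s", s_labels, small_feature_cfg(dim_entity = 4))
  t_spec <- domain_spec("t", t_labels, small_feature_cfg(dim_entity = 8))
  ncfg <- small_net_cfg()

  sv <- build_vocab(pair$source)
  tv <- build_vocab(pair$target)
  set.seed(20)
  sb <- init_bundle(sv, s_labels, s_spec$feature_cfg, ncfg)
  tb0 <- init_bundle(tv, t_labels, t_spec$feature_cfg, ncfg)
  source <- list(bundle = sb, vocab = sv)
  target <- list(bundle = tb0, vocab = tv)

  # empty plan leaves the target untouched
  planA <- build_transfer_plan(s_spec, t_spec, variant = "A")
  resA <- transfer_parameters(source, planA, target)
  expect_identical(resA$bundle, tb0)
  expect_equal(nrow(resA$audit), 0)

  planD <- build_transfer_plan(s_spec, t_spec, variant = "D")
  res <- transfer_parameters(source, planD, target)
  tb <- res$bundle

  # recurrent weights copied; CRF untouched; entity rows untouched
  expect_identical(tb$lstm$fwd$W_hi, sb$lstm$fwd$W_hi)
  expect_identical(tb$crf, tb0$crf)
  t_layout <- channel_layout(t_spec$feature_cfg)
  ent <- t_layout[t_layout$channel == "entity", ]
  expect_identical(tb$lstm$fwd$W_xi[ent$start:ent$end, ],
                   tb0$lstm$fwd$W_xi[ent$start:ent$end, ])
  # shared-channel rows come from the source layout position
  s_layout <- channel_layout(s_spec$feature_cfg)
  dep_s <- s_layout[s_layout$channel == "dep", ]
  dep_t <- t_layout[t_layout$channel == "dep", ]
  expect_identical(tb$lstm$bwd$W_xo[dep_t$start:dep_t$end, ],
                   sb$lstm$bwd$W_xo[dep_s$start:dep_s$end, ])

  # shared label columns copied through name matching, specific ones kept
  j_s <- match("S1", sb$meta$tags); j_t <- match("S1", tb$meta$tags)
  expect_identical(tb$fc$W2[, j_t], sb$fc$W2[, j_s])
  j_spec <- match("T1", tb$meta$tags)
  expect_identical(tb$fc$W2[, j_spec], tb0$fc$W2[, j_spec])

  # word rows copied for common symbols only
  common <- intersect(names(sv$words), names(tv$words))
  w <- setdiff(common, c("<pad>", "<unk>"))[1]
  expect_identical(tb$emb$word[tv$words[[w]], ], sb$emb$word[sv$words[[w]], ])

  # idempotent
  res2 <- transfer_parameters(source, planD, list(bundle = tb, vocab = tv))
  expect_identical(res2$bundle, tb)

  # audit covers every planned entry
  expect_equal(nrow(res$audit), nrow(planD$entries))

  # full copy on identical specs reproduces the source bundle
  s_spec2 <- domain_spec("s", s_labels, small_feature_cfg(dim_entity = 4),
                         domain_dependent = character())
  planB <- build_transfer_plan(s_spec2, s_spec2, variant = "B")
  set.seed(21)
  tb2 <- init_bundle(sv, s_labels, s_spec2$feature_cfg, ncfg)
  resB <- transfer_parameters(list(bundle = sb, vocab = sv), planB,
                              list(bundle = tb2, vocab = sv))
  expect_identical(resB$bundle$lstm, sb$lstm)
  expect_identical(resB$bundle$emb$word, sb$emb$word)
  expect_false(identical(resB$bundle$fc$W2, sb$fc$W2)) # FC not in plan B
})

test_that("hidden-size conflicts on nominally shared blocks are plan errors", {
  pair <- tiny_pair()
  s_labels <- label_set(paste0("S", 1:4))
  s_spec <- domain_spec("s", s_labels, small_feature_cfg())
  t_spec <- domain_spec("t", label_set(c("S1", "X")), small_feature_cfg())
  sv <- build_vocab(pair$source)
  set.seed(22)
  sb <- init_bundle(sv, s_labels, s_spec$feature_cfg, small_net_cfg(hidden = 6))
  tb <- init_bundle(sv, t_spec$labels, t_spec$feature_cfg, small_net_cfg(hidden = 5))
  plan <- build_transfer_plan(s_spec, t_spec, variant = "D")
  expect_error(transfer_parameters(list(bundle = sb, vocab = sv), plan,
                                   list(bundle = tb, vocab = sv)),
               class = "trignet_plan_error")
})

test_that("partitioned middle layer equals the dense layer on concatenated input", {
  set.seed(23)
  for (k in 1:40) {
    d1 <- sample(0:4, 1); d2 <- sample(1:5, 1); H <- sample(1:4, 1)
    xs <- if (d1 > 0) stats::rnorm(d1) else NULL
    xh <- stats::rnorm(d2)
    Ws <- if (d1 > 0) matrix(stats::rnorm(d1 * H), d1, H) else NULL
    Wh <- matrix(stats::rnorm(d2 * H), d2, H)
    b <- stats::rnorm(H)
    act <- if (k %% 2) identity else function(z) pmax(z, 0)
    got <- partitioned_middle_forward(xs, xh, Ws, Wh, b, activation = act)
    dense <- act(drop(c(xs, xh) %*% rbind(Ws, Wh)) + b)
    expect_equal(got, dense, tolerance = 1e-10)
  }
  # consistent permutation of input/weight rows leaves the output unchanged
  x <- stats::rnorm(5); W <- matrix(stats::rnorm(15), 5, 3); b <- stats::rnorm(3)
  p <- sample(5)
  expect_equal(
    partitioned_middle_forward(NULL, x[p], NULL, W[p, ], b),
    partitioned_middle_forward(NULL, x, NULL, W, b),
    tolerance = 1e-12)
  expect_error(partitioned_middle_forward(stats::rnorm(2), x, matrix(0, 3, 3), W, b))
})

test_that("partitioned output layer equals the stacked dense projection", {
  set.seed(24)
  for (k in 1:40) {
    d <- sample(2:5, 1)
    labels <- paste0("L", 1:4)
    sh_lab <- sample(labels, sample(0:4, 1))
    sp_lab <- setdiff(labels, sh_lab)
    mk <- function(ls) {
      if (!length(ls)) return(list(W = NULL, b = NULL))
      W <- matrix(stats::rnorm(length(ls) * d), length(ls), d,
                  dimnames = list(ls, NULL))
      list(W = W, b = stats::setNames(stats::rnorm(length(ls)), ls))
    }
    shared <- mk(sh_lab); specific <- mk(sp_lab)
    x <- stats::rnorm(d)
    got <- partitioned_output_forward(x, shared, specific, labels)
    Wall <- rbind(shared$W, specific$W)[labels, , drop = FALSE]
    ball <- c(shared$b, specific$b)[labels]
    expect_equal(unname(got), unname(drop(Wall %*% x) + ball), tolerance = 1e-10)
  }
  # all labels shared reduces to a plain dense projection
  labels <- c("A", "B")
  W <- matrix(1:4 / 4, 2, 2, dimnames = list(labels, NULL))
  b <- stats::setNames(c(0.1, -0.2), labels)
  got <- partitioned_output_forward(c(1, 2), list(W = W, b = b),
                                    list(W = NULL, b = NULL), labels)
  expect_equal(unname(got), unname(drop(W %*% c(1, 2)) + b), tolerance = 1e-12)
  # a label in neither partition is an error
  expect_error(partitioned_output_forward(c(1, 2), list(W = W, b = b),
                                          list(W = NULL, b = NULL),
                                          c("A", "B", "C")))
})

test_that("source subsampling is a seeded document-level floor subset", {
  pair <- tiny_pair(source_docs = 10)
  src <- pair$source
  expect_identical(subsample_source(src, 1), src)
  expect_equal(nrow(subsample_source(src, 0)), 0)
  sub <- subsample_source(src, 0.75, seed = 3)
  expect_equal(length(unique(sub$doc_id)), 7) # floor(0.75 * 10)
  expect_identical(subsample_source(src, 0.75, seed = 3), sub)
  # document-level: every kept document is complete
  for (d in unique(sub$doc_id)) {
    expect_equal(sum(sub$doc_id == d), sum(src$doc_id == d))
  }
  # the published size arithmetic: floor(0.8 * 950) = 760 documents
  expect_equal(floor(0.8 * 950), 760)
})
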