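# Shared fixtures: small configurations and generated corpora used across
# test files. Everything is built in code, seeded, at dimensions small
# enough for fast CPU runs.

small_feature_cfg <- function(dim_entity = 4, channels = c("word", "pos", "entity", "dep")) {
  feature_config(dim_word = 8, dim_char = 6, dim_pos = 3, dim_entity = dim_entity,
                 dim_dep = 6, dim_char_input = 4, channels = channels)
}

small_net_cfg <- function(hidden = 6) {
  network_config(hidden_size = hidden, fc_dim = 8, init_range = 0.2)
}

tiny_pair <- function(seed = 7, source_docs = 4, target_docs = 3) {
  cfg <- synth_config(
    source_labels = paste0("S", 1:4),
    target_labels = c(paste0("S", 1:2), paste0("T", 1:3)),
    source_docs = source_docs, target_docs = target_docs,
    sentences_per_doc = 4, seed = seed
  )
  generate_domain_pair(cfg)
}

# An independent brute-force CRF oracle: enumerate all L^T paths.
enumerate_crf <- function(emissions, crf) {
  n <- nrow(emissions)
  L <- ncol(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  score_path <- function(p) {
    s <- crf$start[p[1]] + emissions[1, p[1]]
    if (n > 1) {
      for (t in 2:n) s <- s + crf$trans[p[t - 1], p[t]] + emissions[t, p[t]]
    }
    s + crf$stop[p[n]]
  }
  scores <- apply(paths, 1, score_path)
  m <- max(scores)
  list(logZ = m + log(sum(exp(scores - m))),
       best_score = max(scores),
       best_path = paths[which.max(scores), ],
       scores = scores, paths = paths)
}

random_crf <- function(L) {
  list(trans = matrix(stats::rnorm(L * L), L, L),
       start = stats::rnorm(L), stop = stats::rnorm(L))
}
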