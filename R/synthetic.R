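# Seeded synthetic corpora for paired source/target domains.
#
# The generator emulates the statistical structure that matters to the
# transfer setting — overlapping label inventories with shared trigger
# lexicons, domain-specific entity inventories, a controllable fraction of
# context-dependent (ambiguous) trigger words — using synthetic tokens, not
# real biomedical language. Each sentence is background words with triggers
# inserted at a configured rate; an ambiguous trigger word's label is
# decided by a marker word within a two-token window, which forces a tagger
# to model context rather than memorize a lexicon.

#' Synthetic domain-pair configuration
#'
#' @param source_labels,target_labels trigger label inventories; overlap is
#'   implied by shared names, and shared labels get identical trigger
#'   lexicons in both domains
#' @param lexicon_size trigger words per label
#' @param vocab_size number of distinct background words
#' @param ambiguity fraction of trigger words whose label depends on a
#'   marker word within +/-2 tokens
#' @param sent_len integer range (min, max) of sentence lengths in tokens
#' @param trigger_rate expected triggers per sentence (at most 2 are placed)
#' @param source_entities,target_entities per-domain named-entity inventories
#' @param entity_rate fraction of background tokens carrying an entity type
#' @param source_docs,target_docs document counts
#' @param sentences_per_doc sentences per document
#' @param seed integer seed; the same configuration and seed give identical
#'   corpora
#' @return object of class `synth_config`
#' @export
synth_config <- function(source_labels, target_labels,
                         lexicon_size = 4, vocab_size = 120,
                         ambiguity = 0.3, sent_len = c(6, 12),
                         trigger_rate = 1.5,
                         source_entities = c("Protein"),
                         target_entities = c("Protein", "Cell", "Organ", "Tissue"),
                         entity_rate = 0.2,
                         source_docs = 36, target_docs = 10,
                         sentences_per_doc = 5, seed = 1L) {
  if (!length(source_labels) || !length(target_labels)) {
    trignet_abort("label lists must be non-empty")
  }
  if (ambiguity < 0 || ambiguity > 1) trignet_abort("ambiguity must lie in [0, 1]")
  if (trigger_rate > 2) trignet_abort("trigger_rate must be <= 2 (two trigger slots per sentence)")
  if (sent_len[1] < 6) trignet_abort("minimum sentence length is 6 (room for two spaced triggers)")
  if (sent_len[2] < 8) trignet_abort("maximum sentence length must be >= 8 (two-trigger sentences)")
  structure(list(source_labels = as.character(source_labels),
                 target_labels = as.character(target_labels),
                 lexicon_size = lexicon_size, vocab_size = vocab_size,
                 ambiguity = ambiguity, sent_len = sent_len,
                 trigger_rate = trigger_rate,
                 source_entities = source_entities,
                 target_entities = target_entities,
                 entity_rate = entity_rate,
                 source_docs = source_docs, target_docs = target_docs,
                 sentences_per_doc = sentences_per_doc,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Build the union lexicon once so shared labels share trigger words.
build_lexicon <- function(config) {
  labels <- union(config$source_labels, config$target_labels)
  rows <- list()
  w <- 0L
  for (lab in labels) {
    for (k in seq_len(config$lexicon_size)) {
      w <- w + 1L
      rows[[w]] <- tibble::tibble(word = sprintf("trg%03d", w), label = lab)
    }
  }
  lex <- dplyr::bind_rows(rows)
  # Mark a fraction as ambiguous and give each a second label; the realized
  # label of an occurrence is signalled by a marker word.
  n_amb <- round(config$ambiguity * nrow(lex))
  lex$ambiguous <- FALSE
  lex$alt_label <- NA_character_
  if (n_amb > 0) {
    amb_idx <- sample(nrow(lex), n_amb)
    lex$ambiguous[amb_idx] <- TRUE
    for (i in amb_idx) {
      others <- setdiff(labels, lex$label[i])
      lex$alt_label[i] <- if (length(others)) sample(others, 1) else lex$label[i]
    }
  }
  lex
}

marker_word <- function(label) paste0("mk_", label)

gen_sentence <- function(config, lex, domain_labels, entities, bg_words) {
  # number of triggers first: two Bernoulli slots with mean trigger_rate
  p <- config$trigger_rate / 2
  n_trig <- stats::rbinom(1, 2, p)
  # a two-trigger sentence needs length >= 8 so the triggers sit >= 5 apart
  # (their +/-2 marker windows must not overlap)
  lo <- if (n_trig == 2) max(config$sent_len[1], 8L) else config$sent_len[1]
  len <- sample(lo:config$sent_len[2], 1)
  tokens <- sample(bg_words, len, replace = TRUE)
  tags <- rep("O", len)
  # candidate lexicon rows usable in this domain
  usable <- lex[lex$label %in% domain_labels |
                  (lex$ambiguous & lex$alt_label %in% domain_labels), ]
  placed <- integer(0)
  if (n_trig > 0 && nrow(usable) > 0) {
    slots <- if (n_trig == 1) sample(len, 1) else c(2L, len - 1L)
    for (pos in slots) {
      row <- usable[sample(nrow(usable), 1), ]
      choices <- intersect(c(row$label, if (row$ambiguous) row$alt_label),
                           domain_labels)
      lab <- if (length(choices) == 1) choices else sample(choices, 1)
      if (row$ambiguous) {
        off <- sample(c(-2L, -1L, 1L, 2L), 4)
        cand <- pos + off
        ok <- cand >= 1 & cand <= len & tags[pmin(pmax(cand, 1), len)] == "O"
        mpos <- cand[which(ok)[1]]
        if (is.na(mpos)) {
          # no room for a marker: fall back to the word's primary label,
          # or skip the slot when that label is outside this domain
          if (!row$label %in% choices) next
          lab <- row$label
        } else {
          tokens[mpos] <- marker_word(lab)
        }
      }
      tokens[pos] <- row$word
      tags[pos] <- lab
      placed <- c(placed, pos)
    }
  }
  ent <- rep(NA_character_, len)
  bg <- which(tags == "O" & !startsWith(tokens, "mk_"))
  if (length(bg) && config$entity_rate > 0) {
    pick <- bg[stats::runif(length(bg)) < config$entity_rate]
    if (length(pick)) ent[pick] <- sample(entities, length(pick), replace = TRUE)
  }
  # deterministic POS from the token class; dep-context word = left neighbour
  pos_tags <- ifelse(tags != "O", "VB",
                     ifelse(startsWith(tokens, "mk_"), "RB",
                            c("NN", "JJ", "DT")[(nchar(tokens) %% 3) + 1]))
  dep <- c(NA_character_, tokens[-len])
  tibble::tibble(token = tokens, pos = pos_tags, entity = ent,
                 dep_word = dep, tag = tags)
}

gen_domain <- function(config, lex, domain_labels, entities, n_docs, prefix,
                       bg_words) {
  rows <- list()
  for (d in seq_len(n_docs)) {
    for (s in seq_len(config$sentences_per_doc)) {
      sent <- gen_sentence(config, lex, domain_labels, entities, bg_words)
      sent$doc_id <- sprintf("%s%04d", prefix, d)
      sent$sent_id <- s
      sent$token_id <- seq_len(nrow(sent))
      rows[[length(rows) + 1L]] <- sent
    }
  }
  if (!length(rows)) return(empty_corpus())
  as_trig_corpus(dplyr::bind_rows(rows))
}

#' Generate a paired source/target synthetic corpus
#'
#' Draws both domains from one shared trigger lexicon (so overlapping labels
#' share trigger words), with per-domain entity inventories and sizes. The
#' returned ledger records the lexicon and the realized per-label counts;
#' [corpus_stats()] of the emitted corpora matches it exactly.
#'
#' @param config a [synth_config]
#' @return list with `source`, `target` (corpus tibbles) and `ledger`
#'   (list with `lexicon`, `source_counts`, `target_counts`, `config`)
#' @export
generate_domain_pair <- function(config) {
  set.seed(config$seed)
  if (config$lexicon_size * length(unique(c(config$source_labels,
                                            config$target_labels))) < 1) {
    trignet_abort("empty trigger lexicon", class = "trignet_config_error")
  }
  lex <- build_lexicon(config)
  bg_words <- sprintf("w%03d", seq_len(config$vocab_size))
  source <- gen_domain(config, lex, config$source_labels,
                       config$source_entities, config$source_docs, "s",
                       bg_words)
  target <- gen_domain(config, lex, config$target_labels,
                       config$target_entities, config$target_docs, "t",
                       bg_words)
  count_by_label <- function(corpus, labels) {
    tab <- table(factor(corpus$tag[corpus$tag != "O"], levels = labels))
    tibble::tibble(label = labels, n = as.integer(tab))
  }
  ledger <- list(
    lexicon = lex,
    source_counts = count_by_label(source, config$source_labels),
    target_counts = count_by_label(target, config$target_labels),
    config = config
  )
  list(source = source, target = target, ledger = ledger)
}

#' Recover the generating labels of a synthetic sentence
#'
#' The generator is invertible by construction: an unambiguous trigger word
#' maps to its lexicon label; an ambiguous one takes the label of the marker
#' word within two tokens. Background and marker tokens are negative. Serves
#' as the learnability ceiling for models trained on generated data.
#'
#' @param sentence one sentence tibble produced by the generator
#' @param ledger the generator ledger
#' @return character vector of tags
#' @export
oracle_tag <- function(sentence, ledger) {
  lex <- ledger$lexicon
  n <- nrow(sentence)
  tags <- rep("O", n)
  for (i in seq_len(n)) {
    w <- sentence$token[i]
    if (startsWith(w, "mk_")) next
    row <- lex[lex$word == w, ]
    if (nrow(row) == 0) {
      if (startsWith(w, "trg")) {
        trignet_abort(sprintf("word '%s' not in the generator lexicon", w))
      }
      next
    }
    if (!row$ambiguous) {
      tags[i] <- row$label
    } else {
      window <- setdiff(max(1, i - 2):min(n, i + 2), i)
      markers <- sentence$token[window]
      hit <- markers[startsWith(markers, "mk_")]
      cand <- sub("^mk_", "", hit)
      cand <- intersect(cand, c(row$label, row$alt_label))
      if (length(cand)) tags[i] <- cand[1] else tags[i] <- row$label
    }
  }
  tags
}

#' Write a small fixed source/target fixture suite
#'
#' A mini domain pair with the geometry of the published setting: a 9-label
#' source nested in a 19-label target (9 shared labels) and a source/target
#' document ratio of 3.6. Emits both dialects (CoNLL columns and standoff
#' triples) plus the ledger, deterministically from the seed.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed
#' @return invisible list with the generated pair and the file paths
#' @export
make_fixture_suite <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- synth_config(
    source_labels = st09_label_set()$labels,
    target_labels = mlee_label_set()$labels,
    source_docs = 36, target_docs = 10, sentences_per_doc = 5,
    seed = seed
  )
  pair <- generate_domain_pair(cfg)
  paths <- list(
    source_conll = file.path(dir, "source.conll"),
    target_conll = file.path(dir, "target.conll")
  )
  write_conll(pair$source, paths$source_conll)
  write_conll(pair$target, paths$target_conll)
  so_dir <- file.path(dir, "standoff")
  dir.create(so_dir, showWarnings = FALSE)
  for (doc in unique(pair$target$doc_id)[1:2]) {
    so <- corpus_to_standoff(pair$target[pair$target$doc_id == doc, ])
    write_standoff(so, file.path(so_dir, doc))
  }
  jsonlite::write_json(
    list(seed = seed,
         source_counts = pair$ledger$source_counts,
         target_counts = pair$ledger$target_counts),
    file.path(dir, "ledger.json"), dataframe = "rows", auto_unbox = TRUE)
  invisible(list(pair = pair, paths = paths, config = cfg))
}
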