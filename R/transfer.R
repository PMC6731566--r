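# Cross-domain transfer: sharing plans, parameter copying, partitioned
# layers, source subsampling, three-phase training and the ratio sweep.
#
# The generalized scheme partitions every layer's parameters vertically into
# domain-shared and domain-specific blocks. Input-side blocks follow the
# feature channels (shared channels -> shared BiLSTM input-weight rows);
# output-side blocks follow the label overlap (shared labels -> shared
# projection rows). CRF transitions are never transferred by default.

#' Domain specification
#'
#' Everything the transfer planner needs to know about one domain: its name,
#' trigger label set, feature configuration, and which input channels carry
#' domain-dependent information (by default only the named-entity channel,
#' whose inventory and dimension differ between domains).
#'
#' @param name domain name
#' @param labels a [label_set]
#' @param feature_cfg a [feature_config]
#' @param domain_dependent character vector of domain-dependent channels
#' @return object of class `domain_spec`
#' @export
domain_spec <- function(name, labels, feature_cfg,
                        domain_dependent = "entity") {
  stopifnot(inherits(labels, "label_set"), inherits(feature_cfg, "feature_config"))
  domain_dependent <- intersect(domain_dependent, channel_order)
  structure(list(name = name, labels = labels, feature_cfg = feature_cfg,
                 domain_dependent = domain_dependent),
            class = "domain_spec")
}

plan_entry <- function(layer, block, detail = NA_character_) {
  tibble::tibble(layer = layer, block = block, detail = detail)
}

# Channels shareable between two specs: active in both, equal dimension,
# domain-dependent in neither.
shared_channels <- function(source, target) {
  ch <- intersect(source$feature_cfg$channels, target$feature_cfg$channels)
  ch <- setdiff(ch, union(source$domain_dependent, target$domain_dependent))
  ch[source$feature_cfg$dims[ch] == target$feature_cfg$dims[ch]]
}

features_identical <- function(source, target) {
  setequal(source$feature_cfg$channels, target$feature_cfg$channels) &&
    length(source$domain_dependent) == 0 && length(target$domain_dependent) == 0 &&
    all(source$feature_cfg$dims[source$feature_cfg$channels] ==
          target$feature_cfg$dims[source$feature_cfg$channels])
}

bilstm_full_entries <- function(channels) {
  dplyr::bind_rows(
    plan_entry("lstm", "recurrent"),
    plan_entry("lstm", "peephole"),
    plan_entry("lstm", "bias"),
    dplyr::bind_rows(lapply(channels, function(ch) plan_entry("lstm", "input", ch)))
  )
}

#' Build a parameter-sharing plan between two domains
#'
#' Variants mirror the four architectures of the transfer scheme:
#' * `A` — no transfer (empty plan; the single-domain baseline).
#' * `B` — identical input feature sets, disjoint (or ignored) label sets:
#'   all embedding tables and the whole BiLSTM are shared, the
#'   fully-connected layer is not. Requires feature consistency; building a
#'   B plan over inconsistent features is an error.
#' * `C` — inconsistent feature sets: only the lookup tables of
#'   domain-independent channels are shared.
#' * `D` — the generalized plan: domain-independent embedding tables; the
#'   BiLSTM recurrent, peephole and bias blocks plus the input-weight row
#'   groups of shared channels; the fully-connected hidden block; and the
#'   label-projection rows and biases of every shared label. When the label
#'   overlap is empty the plan degenerates exactly to `B` (identical
#'   features) or `C` (inconsistent features): with no shared labels there
#'   is no shared part of the fully-connected layer, and without it an
#'   inconsistent BiLSTM input leaves only the embedding tables.
#'
#' @param source,target [domain_spec] objects
#' @param variant `"A"`, `"B"`, `"C"` or `"D"`
#' @param share_crf experimental: also share CRF transition scores between
#'   shared-label pairs (off by default; transitions are never part of the
#'   published scheme)
#' @return object of class `transfer_plan`
#' @export
build_transfer_plan <- function(source, target, variant = c("D", "A", "B", "C"),
                                share_crf = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(source, "domain_spec"), inherits(target, "domain_spec"))
  sh_ch <- shared_channels(source, target)
  overlap <- compute_label_overlap(source$labels, target$labels)
  entries <- plan_entry(character(), character())[0, ]

  if (variant == "B") {
    if (!features_identical(source, target)) {
      trignet_abort(paste(
        "variant B requires identical input feature sets;",
        "domain-dependent or mismatching channels present"))
    }
    entries <- dplyr::bind_rows(
      dplyr::bind_rows(lapply(sh_ch, function(ch) plan_entry("emb", "table", ch))),
      bilstm_full_entries(sh_ch)
    )
  } else if (variant == "C") {
    entries <- dplyr::bind_rows(lapply(sh_ch, function(ch) plan_entry("emb", "table", ch)))
  } else if (variant == "D") {
    entries <- dplyr::bind_rows(lapply(sh_ch, function(ch) plan_entry("emb", "table", ch)))
    if (length(overlap$shared) > 0) {
      entries <- dplyr::bind_rows(
        entries,
        bilstm_full_entries(sh_ch),
        plan_entry("fc", "hidden"),
        dplyr::bind_rows(lapply(overlap$shared, function(l) plan_entry("fc", "label", l))),
        # the negative tag exists in both inventories, so its projection row
        # belongs to the shared output block whenever the overlap is non-empty
        plan_entry("fc", "negative")
      )
      if (share_crf) entries <- dplyr::bind_rows(entries, plan_entry("crf", "shared_transitions"))
    } else if (features_identical(source, target)) {
      entries <- dplyr::bind_rows(entries, bilstm_full_entries(sh_ch))
    }
  }
  structure(list(variant = variant, source = source, target = target,
                 shared_channels = sh_ch, overlap = overlap,
                 entries = entries),
            class = "transfer_plan")
}

#' @export
print.transfer_plan <- function(x, ...) {
  cat("<transfer_plan> variant", x$variant, ":",
      x$source$name, "->", x$target$name, "\n")
  cat("  shared channels:", paste(x$shared_channels, collapse = ", "), "\n")
  cat("  shared labels:", length(x$overlap$shared),
      " entries:", nrow(x$entries), "\n")
  invisible(x)
}

#' Test whether two plans share exactly the same blocks
#' @param a,b [build_transfer_plan()] results
#' @return TRUE when the entry sets coincide
#' @export
plan_equal <- function(a, b) {
  key <- function(p) sort(paste(p$entries$layer, p$entries$block,
                                ifelse(is.na(p$entries$detail), "", p$entries$detail)))
  identical(key(a), key(b))
}

#' Serialize a plan to JSON
#' @param plan a [build_transfer_plan()] result
#' @param path optional output file
#' @return JSON string (invisibly when written)
#' @export
plan_to_json <- function(plan, path = NULL) {
  obj <- list(
    variant = plan$variant,
    source = plan$source$name, target = plan$target$name,
    shared_channels = plan$shared_channels,
    shared_labels = plan$overlap$shared,
    entries = plan$entries
  )
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# Index map between two symbol vocabularies: rows to copy (src_idx, tgt_idx).
symbol_index_map <- function(src_map, tgt_map) {
  common <- intersect(names(src_map), names(tgt_map))
  list(src = unname(src_map[common]), tgt = unname(tgt_map[common]),
       symbols = common)
}

check_same_dim <- function(a, b, block) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) {
    trignet_abort(sprintf("shape conflict on shared block '%s' (%s vs %s)",
                          block, paste(da, collapse = "x"),
                          paste(db, collapse = "x")),
                  class = "trignet_plan_error")
  }
}

#' Copy shared parameter blocks from a trained source network
#'
#' Applies a [build_transfer_plan()]: every shared block is copied from the
#' source bundle into the target bundle through the plan's index maps
#' (vocabulary rows by symbol, projection rows by label name, channel row
#' groups by layout position). Target-specific blocks keep their
#' initialization; CRF blocks are untouched unless the plan carries the
#' experimental transition entry. The copy is idempotent.
#'
#' @param source a `trignet_model` (or list with `bundle` and `vocab`)
#' @param plan the transfer plan
#' @param target list with the freshly initialized target `bundle` and its
#'   `vocab`
#' @return list with the initialized target `bundle` and an `audit` tibble
#'   (`layer`, `block`, `detail`, `n_copied`)
#' @export
transfer_parameters <- function(source, plan, target) {
  sb <- source$bundle; sv <- source$vocab
  tb <- target$bundle; tv <- target$vocab
  audit <- list()
  note <- function(layer, block, detail, n) {
    audit[[length(audit) + 1L]] <<- tibble::tibble(
      layer = layer, block = block, detail = detail, n_copied = as.integer(n))
  }
  s_layout <- channel_layout(plan$source$feature_cfg)
  t_layout <- channel_layout(plan$target$feature_cfg)

  for (k in seq_len(nrow(plan$entries))) {
    e <- plan$entries[k, ]
    if (e$layer == "emb" && e$block == "table") {
      ch <- e$detail
      if (ch == "char") {
        map <- symbol_index_map(sv$chars, tv$chars)
        tb$emb$char_table[map$tgt, ] <- sb$emb$char_table[map$src, ]
        check_same_dim(sb$emb$char_cell$W_xi, tb$emb$char_cell$W_xi, "emb.char_cell")
        for (p in names(tb$emb$char_cell)) tb$emb$char_cell[[p]] <- sb$emb$char_cell[[p]]
        note("emb", "table", "char",
             length(map$tgt) * ncol(tb$emb$char_table) +
               bundle_cell_size(sb$emb$char_cell))
      } else {
        vslot <- switch(ch, word = "words", pos = "pos", entity = "entity", dep = "dep")
        map <- symbol_index_map(sv[[vslot]], tv[[vslot]])
        check_same_dim(sb$emb[[ch]][1, ], tb$emb[[ch]][1, ], paste0("emb.", ch))
        tb$emb[[ch]][map$tgt, ] <- sb$emb[[ch]][map$src, ]
        note("emb", "table", ch, length(map$tgt) * ncol(tb$emb[[ch]]))
      }
    } else if (e$layer == "lstm" && e$block %in% c("recurrent", "peephole", "bias")) {
      pars <- switch(e$block,
                     recurrent = c("W_hi", "W_hf", "W_hc", "W_ho"),
                     peephole = c("w_ci", "w_cf", "w_co"),
                     bias = c("b_i", "b_f", "b_c", "b_o"))
      n <- 0
      for (dir in c("fwd", "bwd")) {
        for (p in pars) {
          check_same_dim(sb$lstm[[dir]][[p]], tb$lstm[[dir]][[p]],
                         paste("lstm", dir, p, sep = "."))
          tb$lstm[[dir]][[p]] <- sb$lstm[[dir]][[p]]
          n <- n + length(sb$lstm[[dir]][[p]])
        }
      }
      note("lstm", e$block, NA, n)
    } else if (e$layer == "lstm" && e$block == "input") {
      ch <- e$detail
      srow <- s_layout[s_layout$channel == ch, ]
      trow <- t_layout[t_layout$channel == ch, ]
      if (nrow(srow) == 0 || nrow(trow) == 0 || srow$dim != trow$dim) {
        trignet_abort(sprintf("shape conflict on shared block 'lstm.input.%s'", ch),
                      class = "trignet_plan_error")
      }
      n <- 0
      for (dir in c("fwd", "bwd")) {
        for (p in c("W_xi", "W_xf", "W_xc", "W_xo")) {
          if (ncol(sb$lstm[[dir]][[p]]) != ncol(tb$lstm[[dir]][[p]])) {
            trignet_abort(sprintf("shape conflict on shared block 'lstm.%s.%s'", dir, p),
                          class = "trignet_plan_error")
          }
          tb$lstm[[dir]][[p]][trow$start:trow$end, ] <-
            sb$lstm[[dir]][[p]][srow$start:srow$end, ]
          n <- n + srow$dim * ncol(sb$lstm[[dir]][[p]])
        }
      }
      note("lstm", "input", ch, n)
    } else if (e$layer == "fc" && e$block == "hidden") {
      check_same_dim(sb$fc$W1, tb$fc$W1, "fc.W1")
      tb$fc$W1 <- sb$fc$W1
      tb$fc$b1 <- sb$fc$b1
      note("fc", "hidden", NA, length(sb$fc$W1) + length(sb$fc$b1))
    } else if (e$layer == "fc" && e$block == "negative") {
      js <- match(plan$source$labels$negative, sb$meta$tags)
      jt <- match(plan$target$labels$negative, tb$meta$tags)
      tb$fc$W2[, jt] <- sb$fc$W2[, js]
      tb$fc$b2[jt] <- sb$fc$b2[js]
      note("fc", "negative", NA, nrow(sb$fc$W2) + 1L)
    } else if (e$layer == "fc" && e$block == "label") {
      lbl <- e$detail
      js <- match(lbl, sb$meta$tags)
      jt <- match(lbl, tb$meta$tags)
      if (is.na(js) || is.na(jt)) {
        trignet_abort(sprintf("shared label '%s' missing from a tag inventory", lbl),
                      class = "trignet_plan_error")
      }
      if (nrow(sb$fc$W2) != nrow(tb$fc$W2)) {
        trignet_abort("shape conflict on shared block 'fc.W2'",
                      class = "trignet_plan_error")
      }
      tb$fc$W2[, jt] <- sb$fc$W2[, js]
      tb$fc$b2[jt] <- sb$fc$b2[js]
      note("fc", "label", lbl, nrow(sb$fc$W2) + 1L)
    } else if (e$layer == "crf" && e$block == "shared_transitions") {
      sh <- plan$overlap$shared
      js <- match(sh, sb$meta$tags)
      jt <- match(sh, tb$meta$tags)
      tb$crf$trans[jt, jt] <- sb$crf$trans[js, js]
      tb$crf$start[jt] <- sb$crf$start[js]
      tb$crf$stop[jt] <- sb$crf$stop[js]
      note("crf", "shared_transitions", NA, length(js)^2 + 2L * length(js))
    }
  }
  audit <- if (length(audit)) dplyr::bind_rows(audit) else
    tibble::tibble(layer = character(), block = character(),
                   detail = character(), n_copied = integer())
  list(bundle = tb, audit = audit)
}

bundle_cell_size <- function(cell) {
  sum(vapply(cell, length, 0L))
}

#' Dense layer evaluated through a vertical input partition
#'
#' Computes the same output as a dense layer applied to the concatenation
#' `[x_specific; x_shared]` with the weight matrix assembled from the
#' specific and shared row blocks; the bias is a single (shared) parameter
#' vector. This is the middle-layer partition of the generalized scheme.
#'
#' @param x_specific,x_shared input segments (either may be `NULL` / length 0)
#' @param W_specific,W_shared weight blocks, `length(x_part) x n_out`
#' @param b bias vector of length `n_out`
#' @param activation activation function (default identity)
#' @return output vector of length `n_out`
#' @export
partitioned_middle_forward <- function(x_specific, x_shared, W_specific,
                                       W_shared, b, activation = identity) {
  seg <- function(x, W, nm) {
    if (is.null(x) || length(x) == 0) {
      if (!is.null(W) && length(W) > 0) {
        trignet_abort(paste("empty", nm, "input with non-empty weights"))
      }
      return(0)
    }
    if (is.null(W) || nrow(W) != length(x)) {
      trignet_abort(paste("dimension mismatch in", nm, "block"))
    }
    drop(x %*% W)
  }
  a <- seg(x_specific, W_specific, "specific") + seg(x_shared, W_shared, "shared") + b
  activation(a)
}

#' Label-projection layer evaluated through a vertical output partition
#'
#' Each label's score row lives either in the shared block (labels in the
#' overlap, copied between domains) or in the specific block. Stacking the
#' rows in tag order is numerically identical to one dense projection.
#'
#' @param x input vector
#' @param shared,specific lists with `W` (one row per label, rownames are
#'   label names) and `b` (named bias vector)
#' @param labels character vector giving the output label order
#' @param activation activation function (default identity; emission scores
#'   stay linear)
#' @return named score vector in `labels` order
#' @export
partitioned_output_forward <- function(x, shared, specific, labels,
                                       activation = identity) {
  get_row <- function(block) {
    function(l) {
      if (!is.null(block$W) && l %in% rownames(block$W)) {
        list(w = block$W[l, ], b = block$b[[l]])
      } else NULL
    }
  }
  sh <- get_row(shared); sp <- get_row(specific)
  out <- vapply(labels, function(l) {
    row <- sh(l) %||% sp(l)
    if (is.null(row)) {
      trignet_abort(sprintf("label '%s' is in neither output partition", l))
    }
    if (length(row$w) != length(x)) trignet_abort("dimension mismatch in output partition")
    activation(sum(row$w * x) + row$b)
  }, 0)
  stats::setNames(out, labels)
}

#' Subsample a source corpus by document
#'
#' A uniformly random, seeded subset of `floor(ratio * n_documents)` whole
#' documents without replacement — the source-ratio hyperparameter of the
#' transfer scheme operates at document granularity.
#'
#' @param corpus source corpus tibble
#' @param ratio fraction in `[0, 1]`
#' @param seed integer seed (a child seed is derived so the draw is
#'   independent of the caller's RNG usage)
#' @return corpus tibble restricted to the sampled documents
#' @export
subsample_source <- function(corpus, ratio, seed = 1L) {
  if (ratio < 0 || ratio > 1) trignet_abort("ratio must lie in [0, 1]")
  docs <- unique(corpus$doc_id)
  k <- floor(ratio * length(docs))
  if (k == length(docs)) return(corpus)
  set.seed(derive_seed(seed, "subsample"))
  keep <- sample(docs, k)
  corpus[corpus$doc_id %in% keep, ]
}

#' Three-phase transfer training
#'
#' Phase 1 trains the source network on the (subsampled) source corpus,
#' learning its specific and shared parameters; phase 2 copies every shared
#' block into a freshly initialized target network through the plan; phase 3
#' trains on the target corpus with both the target-specific and the
#' transferred shared parameters updated (no freezing, unless
#' `freeze_shared`). With an empty plan phase 1 is skipped and the result is
#' bit-identical to [train_basic()] on the target at the same seed.
#'
#' @param source source-domain corpus
#' @param target_train,target_dev target-domain training and development
#'   corpora (dev drives early stopping and the reported F1)
#' @param plan a [build_transfer_plan()] result
#' @param net_cfg a [network_config] (shared by both networks)
#' @param config a [train_config]; `source_ratio` and `phase1_epochs` govern
#'   phase 1
#' @param freeze_shared keep transferred blocks fixed in phase 3
#'   (off by default, matching the published procedure)
#' @return object of class `trignet_transfer`: `model` (target
#'   `trignet_model`), `source_model` (or `NULL`), `audit`, `report`
#'   (per-phase epoch losses and dev F1), `plan`
#' @export
three_phase_train <- function(source, target_train, target_dev = NULL, plan,
                              net_cfg = network_config(),
                              config = train_config(),
                              freeze_shared = FALSE) {
  source_model <- NULL
  audit <- NULL
  report <- list()
  src <- empty_corpus()

  if (nrow(plan$entries) > 0) {
    src <- subsample_source(source, config$source_ratio, config$seed)
    if (nrow(src) > 0) {
      src_dev <- NULL
      if (config$source_dev_frac > 0) {
        docs <- unique(src$doc_id)
        ndev <- floor(config$source_dev_frac * length(docs))
        if (ndev > 0 && ndev < length(docs)) {
          parts <- split_corpus(src, c(train = length(docs) - ndev, dev = ndev))
          src <- parts$train; src_dev <- parts$dev
        }
      }
      cfg1 <- config
      cfg1$epochs <- config$phase1_epochs
      cfg1$seed <- derive_seed(config$seed, "phase1")
      source_model <- fit_domain(src, plan$source$labels,
                                 plan$source$feature_cfg, net_cfg, cfg1,
                                 dev = src_dev)
      report$phase1 <- dplyr::mutate(source_model$history, phase = 1L,
                                     .before = 1)
    }
  }

  after_init <- if (is.null(source_model)) NULL else function(bundle, vocab) {
    res <- transfer_parameters(source_model, plan,
                               list(bundle = bundle, vocab = vocab))
    audit <<- res$audit
    b <- res$bundle
    if (freeze_shared) attr(b, "freeze_plan") <- plan
    b
  }

  # When parameters are transferred, the target vocabulary also covers the
  # source corpus, so transferred embedding rows of source-only symbols stay
  # addressable at prediction time. Without a transfer the vocabulary comes
  # from the target corpus alone (keeping no-transfer runs identical to
  # train_basic).
  cfg3 <- config
  if (!is.null(source_model) && !is.null(config$phase3_lr)) {
    cfg3$lr <- config$phase3_lr  # fine-tuning rate; only once a transfer happened
  }
  target_model <- fit_domain(target_train, plan$target$labels,
                             plan$target$feature_cfg, net_cfg, cfg3,
                             dev = target_dev, after_init = after_init,
                             vocab_corpus = if (is.null(source_model)) NULL else src)
  report$phase3 <- dplyr::mutate(target_model$history, phase = 3L, .before = 1)

  structure(list(model = target_model, source_model = source_model,
                 audit = audit, plan = plan,
                 report = dplyr::bind_rows(report)),
            class = "trignet_transfer")
}

#' @export
print.trignet_transfer <- function(x, ...) {
  cat("<trignet_transfer> variant", x$plan$variant, "\n")
  if (!is.null(x$audit)) {
    cat("  transferred blocks:", nrow(x$audit),
        " parameters:", sum(x$audit$n_copied), "\n")
  } else cat("  no transfer performed (empty plan)\n")
  invisible(x)
}

#' Source-ratio sweep
#'
#' Runs [three_phase_train()] for every (ratio, seed) pair and reports the
#' mean development-set micro F1 per ratio — the data behind a ratio-effect
#' curve.
#'
#' @inheritParams three_phase_train
#' @param ratios numeric vector of source ratios in `[0, 1]`
#' @param seeds integer vector of seeds to average over
#' @return tibble of class `trignet_ratio_sweep` with columns `ratio`,
#'   `mean_f1`, `sd_f1`, `n_seeds`; per-run detail in `attr(, "runs")`
#' @export
run_ratio_sweep <- function(source, target_train, target_dev, plan,
                            ratios, seeds = 1L,
                            net_cfg = network_config(),
                            config = train_config()) {
  if (any(ratios < 0 | ratios > 1)) trignet_abort("ratios must lie in [0, 1]")
  runs <- list()
  for (r in ratios) {
    for (s in seeds) {
      cfg <- config
      cfg$source_ratio <- r
      cfg$seed <- as.integer(s)
      fit <- three_phase_train(source, target_train, target_dev, plan,
                               net_cfg, cfg)
      f1 <- micro_f1(target_dev, predict_tags(fit$model, target_dev),
                     plan$target$labels)
      runs[[length(runs) + 1L]] <- tibble::tibble(ratio = r, seed = s, f1 = f1)
    }
  }
  runs <- dplyr::bind_rows(runs)
  out <- dplyr::summarise(dplyr::group_by(runs, .data$ratio),
                          mean_f1 = mean(.data$f1),
                          sd_f1 = stats::sd(.data$f1),
                          n_seeds = dplyr::n(), .groups = "drop")
  attr(out, "runs") <- runs
  class(out) <- c("trignet_ratio_sweep", class(out))
  out
}
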