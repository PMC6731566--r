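# Feature channels and the embedding layer.
#
# Each token is represented by the concatenation of up to five channel
# embeddings, in fixed order:
#   word, character (final hidden state of a character-level LSTM), POS,
#   named-entity type, dependency-context word.
# The word and dependency channels may come from pre-trained word2vec tables;
# the character, POS and entity channels are always trained from scratch.

PAD <- "<pad>"
UNK <- "<unk>"
NONE <- "<none>"

channel_order <- c("word", "char", "pos", "entity", "dep")

#' Feature channel configuration
#'
#' Dimensions and activation flags of the five input channels. The published
#' defaults are 200 (word), 100 (char), 50 (POS), 300 (dependency), and an
#' entity dimension of 10 on the molecular-level source domain vs 50 on the
#' multi-level target domain — the entity channel is the domain-dependent one.
#' `dim_char_input` is the size of the per-character embedding fed to the
#' character LSTM (whose hidden size is `dim_char`).
#'
#' @param dim_word,dim_char,dim_pos,dim_entity,dim_dep channel dimensions
#' @param dim_char_input character-embedding input dimension
#' @param channels which channels are active, a subset of
#'   `c("word", "char", "pos", "entity", "dep")`
#' @return object of class `feature_config`
#' @examples
#' total_dim(feature_config(dim_entity = 10)) # 660 (source-domain default)
#' total_dim(feature_config(dim_entity = 50)) # 700 (target-domain default)
#' @export
feature_config <- function(dim_word = 200, dim_char = 100, dim_pos = 50,
                           dim_entity = 50, dim_dep = 300,
                           dim_char_input = 25,
                           channels = channel_order) {
  channels <- match.arg(channels, channel_order, several.ok = TRUE)
  dims <- c(word = dim_word, char = dim_char, pos = dim_pos,
            entity = dim_entity, dep = dim_dep)
  if (any(dims[channels] <= 0)) trignet_abort("active channel dimensions must be > 0")
  structure(list(dims = dims, channels = channels,
                 dim_char_input = dim_char_input),
            class = "feature_config")
}

#' Channel layout of a feature configuration
#'
#' The position of each active channel inside the concatenated input vector.
#' Row groups of the BiLSTM input weights follow this layout, which is what
#' the vertical parameter partition addresses.
#'
#' @param config a [feature_config]
#' @return tibble with columns `channel`, `dim`, `start`, `end` (1-based,
#'   inclusive column ranges)
#' @export
channel_layout <- function(config) {
  ch <- intersect(channel_order, config$channels)
  d <- unname(config$dims[ch])
  ends <- cumsum(d)
  tibble::tibble(channel = ch, dim = d, start = ends - d + 1L, end = ends)
}

#' Total input dimension of a feature configuration
#' @param config a [feature_config]
#' @return sum of the active channel dimensions
#' @export
total_dim <- function(config) sum(config$dims[config$channels])

# ---------------------------------------------------------------------------
# Vocabulary
# ---------------------------------------------------------------------------

make_symbol_map <- function(symbols) {
  symbols <- setdiff(unique(symbols), c(PAD, UNK))
  stats::setNames(seq_len(length(symbols) + 2L), c(PAD, UNK, symbols))
}

#' Build symbol vocabularies from a corpus
#'
#' Dense symbol-to-index maps for words, characters, POS tags, entity types
#' and dependency-context words, each with reserved `<pad>` (index 1) and
#' `<unk>` (index 2) entries. `min_count` applies to the open-class maps
#' (words and dependency words); rarer symbols fold to `<unk>` at lookup
#' time. Absent features (`NA`) map to the `<none>` symbol.
#'
#' @param corpus a corpus tibble
#' @param min_count minimum frequency for a word / dep-word to get its own row
#' @return object of class `trig_vocab`: list of named integer vectors
#'   `words`, `chars`, `pos`, `entity`, `dep`
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  freq_keep <- function(x) {
    x <- x[!is.na(x)]
    tab <- table(x)
    names(tab)[tab >= min_count]
  }
  words <- freq_keep(corpus$token)
  deps <- c(NONE, freq_keep(corpus$dep_word))
  chars <- if (nrow(corpus)) unique(unlist(strsplit(corpus$token, ""), use.names = FALSE)) else character()
  pos <- c(NONE, unique(corpus$pos[!is.na(corpus$pos)]))
  ents <- c(NONE, unique(corpus$entity[!is.na(corpus$entity)]))
  structure(list(
    words = make_symbol_map(words),
    chars = make_symbol_map(chars),
    pos = make_symbol_map(pos),
    entity = make_symbol_map(ents),
    dep = make_symbol_map(deps)
  ), class = "trig_vocab")
}

#' @export
print.trig_vocab <- function(x, ...) {
  cat("<trig_vocab>",
      paste(sprintf("%s=%d", names(x), vapply(x, length, 0L)), collapse = " "),
      "\n")
  invisible(x)
}

# Word lookup with lowercase fallback before <unk>.
lookup_word <- function(map, w) {
  i <- map[w]
  if (!is.na(i)) return(unname(i))
  i <- map[tolower(w)]
  if (!is.na(i)) return(unname(i))
  unname(map[[UNK]])
}

lookup_symbol <- function(map, s) {
  if (is.na(s)) s <- NONE
  i <- map[s]
  if (is.na(i)) unname(map[[UNK]]) else unname(i)
}

lookup_chars <- function(map, w) {
  idx <- map[strsplit(w, "")[[1]]]
  idx[is.na(idx)] <- map[[UNK]]
  unname(idx)
}

# ---------------------------------------------------------------------------
# Embedding tables
# ---------------------------------------------------------------------------

init_matrix <- function(nrow, ncol, range = 0.05) {
  matrix(stats::runif(nrow * ncol, -range, range), nrow, ncol)
}

#' Initialize the embedding tables of one domain
#'
#' Uniform random initialization in `[-range, range]` for every lookup table,
#' plus the character-LSTM cell. Pre-trained word / dependency tables can be
#' overlaid afterwards with [apply_pretrained()]. Draws from the current RNG
#' stream — seed outside for reproducibility.
#'
#' @param vocab a [build_vocab()] result
#' @param config a [feature_config]
#' @param range half-width of the uniform initialization interval
#' @return list of class `embedding_tables`: matrices `word`, `pos`,
#'   `entity`, `dep` (rows = vocab indices), `char_table`, and `char_cell`
#'   (character-LSTM parameters); attributes record which tables are frozen
#' @export
init_embedding_tables <- function(vocab, config, range = 0.05) {
  ch <- config$channels
  tabs <- list()
  if ("word" %in% ch) tabs$word <- init_matrix(length(vocab$words), config$dims[["word"]], range)
  if ("char" %in% ch) {
    tabs$char_table <- init_matrix(length(vocab$chars), config$dim_char_input, range)
    tabs$char_cell <- init_lstm_cell(config$dim_char_input, config$dims[["char"]], range)
  }
  if ("pos" %in% ch) tabs$pos <- init_matrix(length(vocab$pos), config$dims[["pos"]], range)
  if ("entity" %in% ch) tabs$entity <- init_matrix(length(vocab$entity), config$dims[["entity"]], range)
  if ("dep" %in% ch) tabs$dep <- init_matrix(length(vocab$dep), config$dims[["dep"]], range)
  structure(tabs, class = "embedding_tables", frozen = character())
}

#' Character-LSTM embedding of one word
#'
#' Runs a unidirectional LSTM over the word's character embeddings and
#' returns the final hidden state — the orthographic channel of the input
#' vector. Deterministic given parameters; every component lies in (-1, 1).
#'
#' @param word a non-empty string
#' @param tables an [init_embedding_tables()] result (needs `char_table`,
#'   `char_cell`)
#' @param vocab a [build_vocab()] result
#' @return numeric vector of length `dim_char`
#' @export
char_lstm_embed <- function(word, tables, vocab) {
  if (!nzchar(word)) trignet_abort("char_lstm_embed: empty word")
  idx <- lookup_chars(vocab$chars, word)
  X <- tables$char_table[idx, , drop = FALSE]
  run <- lstm_run(X, tables$char_cell)
  run$H[nrow(X), ]
}

#' Embed one token
#'
#' Concatenates the active channel embeddings in fixed order
#' `[word; char; POS; entity; dep]`. Unknown symbols fold to `<unk>`; the
#' word channel tries the lowercased form first.
#'
#' @param token one corpus row (list or single-row tibble with `token`,
#'   `pos`, `entity`, `dep_word`)
#' @param tables embedding tables
#' @param vocab vocabulary
#' @param config feature configuration
#' @return numeric vector of length `total_dim(config)`
#' @export
embed_token <- function(token, tables, vocab, config) {
  surface <- token$token
  pos <- token$pos %||% NA_character_
  entity <- token$entity %||% NA_character_
  dep_word <- token$dep_word %||% NA_character_
  sent <- tibble::tibble(token = surface, pos = pos, entity = entity,
                         dep_word = dep_word)
  embed_sentence(sent, tables, vocab, config)$X[1, ]
}

# Embed a sentence tibble -> list(X = T x D matrix, cache for backprop).
embed_sentence <- function(sentence, tables, vocab, config, cache = FALSE) {
  n <- nrow(sentence)
  layout <- channel_layout(config)
  X <- matrix(0, n, total_dim(config))
  idx <- list()
  char_runs <- if (cache) vector("list", n) else NULL
  for (row in seq_len(nrow(layout))) {
    ch <- layout$channel[row]
    cols <- layout$start[row]:layout$end[row]
    if (ch == "word") {
      ii <- vapply(sentence$token, function(w) lookup_word(vocab$words, w), 0L)
      X[, cols] <- tables$word[ii, , drop = FALSE]
      idx$word <- ii
    } else if (ch == "pos") {
      ii <- vapply(sentence$pos, function(s) lookup_symbol(vocab$pos, s), 0L)
      X[, cols] <- tables$pos[ii, , drop = FALSE]
      idx$pos <- ii
    } else if (ch == "entity") {
      ii <- vapply(sentence$entity, function(s) lookup_symbol(vocab$entity, s), 0L)
      X[, cols] <- tables$entity[ii, , drop = FALSE]
      idx$entity <- ii
    } else if (ch == "dep") {
      ii <- vapply(sentence$dep_word, function(s) lookup_symbol(vocab$dep, s), 0L)
      X[, cols] <- tables$dep[ii, , drop = FALSE]
      idx$dep <- ii
    } else if (ch == "char") {
      cidx <- lapply(sentence$token, function(w) lookup_chars(vocab$chars, w))
      idx$char <- cidx
      for (t in seq_len(n)) {
        Xc <- tables$char_table[cidx[[t]], , drop = FALSE]
        run <- lstm_run(Xc, tables$char_cell, cache = cache)
        X[t, cols] <- run$H[nrow(Xc), ]
        if (cache) char_runs[[t]] <- run
      }
    }
  }
  list(X = X, idx = idx, char_runs = char_runs, layout = layout)
}

# ---------------------------------------------------------------------------
# word2vec text format
# ---------------------------------------------------------------------------

#' Read a word2vec text-format embedding table
#'
#' Expects the standard header line `"N D"` followed by `N` rows
#' `"word v1 ... vD"`.
#'
#' @param path file path
#' @param expected_dim required embedding dimension; a mismatching header or
#'   row is a parse error
#' @return numeric matrix with words as rownames
#' @export
load_word2vec_text <- function(path, expected_dim) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) trignet_abort("empty word2vec file", class = "trignet_parse_error")
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    trignet_abort("malformed word2vec header (expected 'N D')",
                  class = "trignet_parse_error")
  }
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (d != expected_dim) {
    trignet_abort(sprintf("word2vec dimension %d != expected %d", d, expected_dim),
                  class = "trignet_parse_error")
  }
  if (length(lines) - 1L < n) {
    trignet_abort("word2vec file shorter than its header claims",
                  class = "trignet_parse_error")
  }
  words <- character(n)
  mat <- matrix(0, n, d)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    if (length(fields) != d + 1L) {
      trignet_abort(sprintf("word2vec row %d: expected %d values, found %d",
                            i, d, length(fields) - 1L),
                    class = "trignet_parse_error")
    }
    words[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals)) {
      trignet_abort(sprintf("word2vec row %d: non-numeric value", i),
                    class = "trignet_parse_error")
    }
    mat[i, ] <- vals
  }
  rownames(mat) <- words
  mat
}

#' Write a word2vec text-format embedding table
#' @param mat numeric matrix with words as rownames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_word2vec_text <- function(mat, path) {
  lines <- c(paste(nrow(mat), ncol(mat)),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(rownames(mat)[i],
                     paste(formatC(mat[i, ], format = "g", digits = 17),
                           collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Overlay a pre-trained table onto an initialized embedding table
#'
#' Rows of vocabulary symbols found in the pre-trained table are replaced;
#' absent symbols keep their random initialization and are reported. The
#' overlaid channel is frozen (excluded from gradient updates) by default,
#' matching the treatment of pre-trained lookups as fixed features.
#'
#' @param tables an [init_embedding_tables()] result
#' @param vocab the matching vocabulary
#' @param pretrained matrix from [load_word2vec_text()]
#' @param channel `"word"` or `"dep"`
#' @param freeze freeze the channel after overlay?
#' @return list with updated `tables` and a `coverage` report
#'   (`found`, `missing`, `fraction`)
#' @export
apply_pretrained <- function(tables, vocab, pretrained, channel = c("word", "dep"),
                             freeze = TRUE) {
  channel <- match.arg(channel)
  map <- if (channel == "word") vocab$words else vocab$dep
  tab <- tables[[channel]]
  if (ncol(pretrained) != ncol(tab)) {
    trignet_abort("pre-trained dimension does not match the configured channel dimension")
  }
  syms <- setdiff(names(map), c(PAD, UNK))
  found <- syms[syms %in% rownames(pretrained)]
  for (s in found) tab[map[[s]], ] <- pretrained[s, ]
  tables[[channel]] <- tab
  if (freeze) attr(tables, "frozen") <- union(attr(tables, "frozen"), channel)
  list(tables = tables,
       coverage = list(found = found, missing = setdiff(syms, found),
                       fraction = if (length(syms)) length(found) / length(syms) else 1))
}
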