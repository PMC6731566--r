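# Corpus representation and I/O.
#
# A corpus is a token-level tibble with one row per token:
#   doc_id (chr), sent_id (int within doc), token_id (int within sentence),
#   token, pos, entity, dep_word, tag (chr; NA where a feature is absent).
# Two on-disk dialects are supported: BioNLP standoff triples (.txt/.a1/.a2)
# and CoNLL-style column files with blank-line sentence breaks.

corpus_columns <- c("doc_id", "sent_id", "token_id",
                    "token", "pos", "entity", "dep_word", "tag")

#' Construct / validate a token-level corpus tibble
#'
#' @param tokens a data frame with at least columns `doc_id`, `sent_id`,
#'   `token_id`, `token`, `tag`; missing feature columns (`pos`, `entity`,
#'   `dep_word`) are added as `NA`
#' @param domain optional domain name, stored as an attribute
#' @return a tibble with the canonical column set
#' @export
as_trig_corpus <- function(tokens, domain = NULL) {
  tokens <- tibble::as_tibble(tokens)
  need <- c("doc_id", "sent_id", "token_id", "token", "tag")
  miss <- setdiff(need, names(tokens))
  if (length(miss)) trignet_abort(paste("corpus is missing columns:", paste(miss, collapse = ", ")))
  for (col in c("pos", "entity", "dep_word")) {
    if (!col %in% names(tokens)) tokens[[col]] <- NA_character_
  }
  if (any(!nzchar(tokens$token))) trignet_abort("tokens must be non-empty strings")
  out <- tokens[, corpus_columns]
  if (!is.null(domain)) attr(out, "domain") <- domain
  out
}

empty_corpus <- function() {
  tibble::tibble(
    doc_id = character(), sent_id = integer(), token_id = integer(),
    token = character(), pos = character(), entity = character(),
    dep_word = character(), tag = character()
  )
}

# Iterate over sentences: returns a list of tibbles in document/sentence order.
corpus_sentences <- function(corpus) {
  if (nrow(corpus) == 0) return(list())
  key <- paste(corpus$doc_id, corpus$sent_id, sep = "\r")
  split(corpus, factor(key, levels = unique(key)))
}

#' Tokenize a line of text with character offsets
#'
#' Splits on whitespace and punctuation: maximal runs of word characters
#' (letters, digits, underscore, apostrophe) are tokens, and every other
#' non-space character is a single-character token. Offsets are 0-based,
#' half-open into the input string. The tokenizer is deliberately simple —
#' corpora with pre-tokenized columns bypass it entirely.
#'
#' @param text a single string (one sentence / line)
#' @param offset character offset of the start of `text` within the document
#' @return tibble with columns `token`, `start`, `end`
#' @export
tokenize_text <- function(text, offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[A-Za-z0-9_']+|[^A-Za-z0-9_'[:space:]]", text)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L + as.integer(offset)
  lens <- attr(m, "match.length")
  tibble::tibble(
    token = regmatches(text, gregexpr("[A-Za-z0-9_']+|[^A-Za-z0-9_'[:space:]]", text))[[1]],
    start = starts,
    end = starts + as.integer(lens)
  )
}

# ---------------------------------------------------------------------------
# BioNLP standoff dialect
# ---------------------------------------------------------------------------

parse_standoff_lines <- function(lines, text, what) {
  lines <- lines[nzchar(lines)]
  keep <- grepl("^T", lines)
  other <- lines[!keep]
  bad <- other[!grepl("^[EMRAN*#]", other)]
  if (length(bad)) {
    trignet_abort(sprintf("malformed %s line %d: %s", what,
                          which(lines == bad[1])[1], bad[1]),
                  class = "trignet_parse_error")
  }
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble::tibble(id = character(), type = character(),
                          start = integer(), end = integer(),
                          surface = character()))
  }
  rx <- "^(T[0-9]+)\t([^ \t]+) ([0-9]+) ([0-9]+)\t(.*)$"
  ok <- grepl(rx, lines)
  if (any(!ok)) {
    i <- which(!ok)[1]
    trignet_abort(sprintf("malformed %s line %d: %s", what, i, lines[i]),
                  class = "trignet_parse_error")
  }
  ann <- tibble::tibble(
    id = sub(rx, "\\1", lines),
    type = sub(rx, "\\2", lines),
    start = as.integer(sub(rx, "\\3", lines)),
    end = as.integer(sub(rx, "\\4", lines)),
    surface = sub(rx, "\\5", lines)
  )
  n <- nchar(text)
  for (i in seq_len(nrow(ann))) {
    if (ann$start[i] < 0 || ann$start[i] >= ann$end[i] || ann$end[i] > n) {
      trignet_abort(sprintf("%s annotation %s: offsets [%d,%d) outside text of length %d",
                            what, ann$id[i], ann$start[i], ann$end[i], n),
                    class = "trignet_integrity_error")
    }
    slice <- substr(text, ann$start[i] + 1L, ann$end[i])
    if (!identical(slice, ann$surface[i])) {
      trignet_abort(sprintf("%s annotation %s: surface '%s' does not match text slice '%s'",
                            ann$id[i], what, ann$surface[i], slice),
                    class = "trignet_integrity_error")
    }
  }
  ann
}

#' Read a BioNLP standoff document
#'
#' Parses the `.a1` (entity) and `.a2` (trigger) annotation content against
#' the raw text. Only `T` lines are interpreted; event (`E`), modification and
#' relation lines are skipped. Every annotation is checked against the text:
#' offsets are 0-based half-open and the recorded surface string must equal
#' the covered text slice.
#'
#' @param text raw document text (single string)
#' @param a1 content of the `.a1` file (string with embedded newlines, or
#'   character vector of lines); `""` for none
#' @param a2 content of the `.a2` file, same conventions
#' @return list with `text`, `entities` and `triggers` tibbles
#'   (`id`, `type`, `start`, `end`, `surface`)
#' @export
read_standoff <- function(text, a1 = "", a2 = "") {
  split_lines <- function(x) {
    if (length(x) <= 1L) x <- unlist(strsplit(x %||% "", "\n", fixed = TRUE))
    x
  }
  list(
    text = text,
    entities = parse_standoff_lines(split_lines(a1), text, ".a1"),
    triggers = parse_standoff_lines(split_lines(a2), text, ".a2")
  )
}

#' @rdname read_standoff
#' @param stem path prefix: reads `<stem>.txt`, `<stem>.a1`, `<stem>.a2`
#'   (missing annotation files are treated as empty)
#' @export
read_standoff_files <- function(stem) {
  read_file <- function(path, required = FALSE) {
    if (!file.exists(path)) {
      if (required) trignet_abort(paste("missing file:", path), class = "trignet_io_error")
      return("")
    }
    paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  read_standoff(
    text = read_file(paste0(stem, ".txt"), required = TRUE),
    a1 = read_file(paste0(stem, ".a1")),
    a2 = read_file(paste0(stem, ".a2"))
  )
}

format_standoff_lines <- function(ann, prefix = "T") {
  if (nrow(ann) == 0) return(character())
  sprintf("%s\t%s %d %d\t%s", ann$id, ann$type, ann$start, ann$end, ann$surface)
}

#' Write a BioNLP standoff document
#'
#' Inverse of [read_standoff()]: serializes entity and trigger annotation
#' tibbles back to `.a1`/`.a2` line format.
#'
#' @param doc a list as returned by [read_standoff()]
#' @param stem if given, writes `<stem>.txt`, `<stem>.a1`, `<stem>.a2` and
#'   returns the paths invisibly; otherwise returns the three contents
#' @return list with `text`, `a1`, `a2` strings (or file paths, invisibly)
#' @export
write_standoff <- function(doc, stem = NULL) {
  out <- list(
    text = doc$text,
    a1 = paste(format_standoff_lines(doc$entities), collapse = "\n"),
    a2 = paste(format_standoff_lines(doc$triggers), collapse = "\n")
  )
  if (is.null(stem)) return(out)
  writeLines(out$text, paste0(stem, ".txt"))
  writeLines(out$a1[nzchar(out$a1)], paste0(stem, ".a1"))
  writeLines(out$a2[nzchar(out$a2)], paste0(stem, ".a2"))
  invisible(paste0(stem, c(".txt", ".a1", ".a2")))
}

#' Project span annotations onto token tags
#'
#' Assigns each token the type of the trigger span it overlaps, and the
#' negative tag otherwise. A trigger spanning several tokens types each of
#' them (raw type-per-token scheme, no BIO prefixes). A token overlapping two
#' spans of different types is an annotation conflict: the default is to
#' raise an error; `ambiguous = "first"` keeps the first annotation's type.
#'
#' @param tokens tibble with columns `token`, `start`, `end` (0-based,
#'   half-open, non-overlapping, sorted)
#' @param annotations tibble with columns `type`, `start`, `end`
#' @param negative the negative tag
#' @param ambiguous conflict policy: `"error"` or `"first"`
#' @return character vector of tags, one per token
#' @export
annotations_to_tags <- function(tokens, annotations, negative = "O",
                                ambiguous = c("error", "first")) {
  ambiguous <- match.arg(ambiguous)
  tags <- rep(negative, nrow(tokens))
  if (is.null(annotations) || nrow(annotations) == 0) return(tags)
  for (i in seq_len(nrow(tokens))) {
    hit <- which(annotations$start < tokens$end[i] & annotations$end > tokens$start[i])
    if (!length(hit)) next
    types <- unique(annotations$type[hit])
    if (length(types) > 1L && ambiguous == "error") {
      trignet_abort(sprintf(
        "token '%s' [%d,%d) overlaps triggers of different types: %s",
        tokens$token[i], tokens$start[i], tokens$end[i],
        paste(types, collapse = ", ")), class = "trignet_ambiguity_error")
    }
    tags[i] <- annotations$type[hit[1]]
  }
  tags
}

#' Convert a standoff document to a token-level corpus
#'
#' Sentences are the non-empty lines of the raw text; tokens come from
#' [tokenize_text()] with document-level offsets. Trigger types become the
#' `tag` column and entity types the `entity` column; POS and dependency
#' columns (not present in standoff) are `NA`.
#'
#' @inheritParams annotations_to_tags
#' @param doc list as from [read_standoff()]
#' @param doc_id document identifier for the corpus rows
#' @return a corpus tibble
#' @export
standoff_to_corpus <- function(doc, doc_id = "d1", negative = "O",
                               ambiguous = c("error", "first")) {
  ambiguous <- match.arg(ambiguous)
  lines <- unlist(strsplit(doc$text, "\n", fixed = TRUE))
  offset <- 0L
  out <- list()
  sent <- 0L
  for (line in lines) {
    toks <- tokenize_text(line, offset = offset)
    offset <- offset + nchar(line) + 1L # + newline
    if (nrow(toks) == 0) next
    sent <- sent + 1L
    tags <- annotations_to_tags(toks, doc$triggers, negative = negative,
                                ambiguous = ambiguous)
    ents <- annotations_to_tags(toks, doc$entities, negative = NA_character_,
                                ambiguous = ambiguous)
    out[[sent]] <- tibble::tibble(
      doc_id = doc_id, sent_id = sent, token_id = seq_len(nrow(toks)),
      token = toks$token, pos = NA_character_, entity = ents,
      dep_word = NA_character_, tag = tags
    )
  }
  if (!length(out)) return(empty_corpus())
  dplyr::bind_rows(out)
}

#' Convert one document of a corpus to a standoff triple
#'
#' Reconstructs raw text by joining tokens with single spaces (one sentence
#' per line) and emits trigger (`tag` column) and entity (`entity` column)
#' annotations. Maximal runs of adjacent tokens sharing a type are grouped
#' into one span — the only place the per-token tag scheme is re-spanned.
#'
#' @param corpus a corpus tibble (rows of a single document)
#' @param negative the negative tag in the `tag` column
#' @return list with `text`, `entities`, `triggers` as in [read_standoff()]
#' @export
corpus_to_standoff <- function(corpus, negative = "O") {
  if (length(unique(corpus$doc_id)) > 1L) {
    trignet_abort("corpus_to_standoff expects a single document")
  }
  sents <- corpus_sentences(corpus)
  text_lines <- character(length(sents))
  trig <- list(); ent <- list()
  offset <- 0L
  for (k in seq_along(sents)) {
    s <- sents[[k]]
    starts <- integer(nrow(s)); ends <- integer(nrow(s))
    pos <- offset
    for (i in seq_len(nrow(s))) {
      starts[i] <- pos
      ends[i] <- pos + nchar(s$token[i])
      pos <- ends[i] + 1L # single space
    }
    text_lines[k] <- paste(s$token, collapse = " ")
    offset <- offset + nchar(text_lines[k]) + 1L # newline
    tagv <- ifelse(s$tag == negative, NA_character_, s$tag)
    trig <- c(trig, span_collect(tagv, starts, ends))
    ent <- c(ent, span_collect(s$entity, starts, ends))
  }
  text <- paste(text_lines, collapse = "\n")
  mk <- function(spans, prefix) {
    if (!length(spans)) {
      return(tibble::tibble(id = character(), type = character(),
                            start = integer(), end = integer(),
                            surface = character()))
    }
    tibble::tibble(
      id = paste0("T", seq_along(spans)),
      type = vapply(spans, `[[`, "", "type"),
      start = vapply(spans, `[[`, 0L, "start"),
      end = vapply(spans, `[[`, 0L, "end"),
      surface = vapply(spans, function(x) substr(text, x$start + 1L, x$end), "")
    )
  }
  list(text = text, entities = mk(ent), triggers = mk(trig))
}

# Collect maximal adjacent same-value runs as [start, end) spans.
span_collect <- function(values, starts, ends) {
  spans <- list()
  n <- length(values)
  i <- 1L
  while (i <= n) {
    if (is.na(values[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(values[j + 1L]) && values[j + 1L] == values[i] &&
           starts[j + 1L] == ends[j] + 1L) j <- j + 1L
    spans[[length(spans) + 1L]] <- list(type = values[i], start = starts[i], end = ends[j])
    i <- j + 1L
  }
  spans
}

# ---------------------------------------------------------------------------
# CoNLL-style column dialect
# ---------------------------------------------------------------------------

conll_default_schema <- c("token", "pos", "entity", "dep_word", "tag")

#' Read a CoNLL-style column corpus
#'
#' One token per line, tab-separated columns in the order given by `schema`,
#' blank lines between sentences, and optional `#doc <id>` comment lines
#' opening a new document (a single unnamed document is assumed otherwise).
#' The placeholder `_` reads as `NA` (absent feature).
#'
#' @param input a file path, or a character vector of lines
#' @param schema column order; any subset of
#'   `c("token", "pos", "entity", "dep_word", "tag")` containing `"token"`
#' @return a corpus tibble
#' @export
read_conll <- function(input, schema = conll_default_schema) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- if (length(input) == 1L) unlist(strsplit(input, "\n", fixed = TRUE)) else input
  }
  if (!"token" %in% schema) trignet_abort("schema must contain 'token'")
  rows <- list()
  doc <- "d1"; sent <- 0L; tok <- 0L; in_sentence <- FALSE
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (grepl("^#doc\\b", line)) {
      doc <- sub("^#doc[ \t]+", "", line)
      sent <- 0L; in_sentence <- FALSE
      next
    }
    if (!nzchar(trimws(line))) { in_sentence <- FALSE; next }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(schema)) {
      trignet_abort(sprintf("line %d: expected %d columns, found %d",
                            k, length(schema), length(fields)),
                    class = "trignet_parse_error")
    }
    if (!in_sentence) { sent <- sent + 1L; tok <- 0L; in_sentence <- TRUE }
    tok <- tok + 1L
    rec <- stats::setNames(as.list(fields), schema)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = doc, sent_id = sent, token_id = tok,
      token = rec$token,
      pos = na_if_placeholder(rec$pos),
      entity = na_if_placeholder(rec$entity),
      dep_word = na_if_placeholder(rec$dep_word),
      tag = rec$tag %||% NA_character_
    )
  }
  if (!length(rows)) return(empty_corpus())
  dplyr::bind_rows(rows)
}

na_if_placeholder <- function(x) {
  if (is.null(x) || identical(x, "_")) NA_character_ else x
}

#' Write a CoNLL-style column corpus
#'
#' Inverse of [read_conll()]: emits `#doc <id>` headers, tab-separated
#' columns per `schema`, `_` for `NA` features and blank lines between
#' sentences. `read_conll(write_conll(x))` is the identity on well-formed
#' corpora.
#'
#' @param corpus a corpus tibble
#' @param path optional output file; if `NULL` the lines are returned
#' @inheritParams read_conll
#' @return the lines (invisibly when written to `path`)
#' @export
write_conll <- function(corpus, path = NULL, schema = conll_default_schema) {
  lines <- character()
  for (doc in unique(corpus$doc_id)) {
    lines <- c(lines, paste("#doc", doc))
    dsub <- corpus[corpus$doc_id == doc, ]
    for (s in unique(dsub$sent_id)) {
      ssub <- dsub[dsub$sent_id == s, ]
      cols <- lapply(schema, function(col) {
        v <- ssub[[col]]
        ifelse(is.na(v), "_", v)
      })
      lines <- c(lines, do.call(paste, c(cols, sep = "\t")), "")
    }
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# ---------------------------------------------------------------------------
# Statistics and subsetting
# ---------------------------------------------------------------------------

#' Corpus summary statistics
#'
#' Documents, sentences, word (token) and trigger counts, with a per-type
#' trigger breakdown — the shape of the published corpus statistics tables.
#'
#' @param corpus a corpus tibble
#' @param negative the negative tag
#' @return list with scalars `documents`, `sentences`, `words`,
#'   `triggers`, and tibble `per_type` (`type`, `n`)
#' @export
corpus_stats <- function(corpus, negative = "O") {
  if (nrow(corpus) == 0) {
    return(list(documents = 0L, sentences = 0L, words = 0L, triggers = 0L,
                per_type = tibble::tibble(type = character(), n = integer())))
  }
  trig <- corpus$tag[!is.na(corpus$tag) & corpus$tag != negative]
  per_type <- tibble::as_tibble(table(type = trig), .name_repair = "minimal")
  names(per_type) <- c("type", "n")
  per_type$type <- as.character(per_type$type)
  per_type$n <- as.integer(per_type$n)
  per_type <- dplyr::arrange(per_type, .data$type)
  list(
    documents = length(unique(corpus$doc_id)),
    sentences = nrow(dplyr::distinct(corpus, .data$doc_id, .data$sent_id)),
    words = nrow(corpus),
    triggers = length(trig),
    per_type = per_type
  )
}

#' Split a corpus by document
#'
#' Deterministically assigns whole documents (in first-appearance order) to
#' named parts of the requested sizes; useful for carving train/dev splits
#' out of generated corpora.
#'
#' @param corpus a corpus tibble
#' @param sizes named integer vector of document counts, e.g.
#'   `c(train = 10, dev = 4)`; must sum to at most the number of documents
#' @return named list of corpus tibbles
#' @export
split_corpus <- function(corpus, sizes) {
  docs <- unique(corpus$doc_id)
  if (sum(sizes) > length(docs)) trignet_abort("split sizes exceed document count")
  out <- list()
  at <- 1L
  for (nm in names(sizes)) {
    take <- docs[seq.int(at, length.out = sizes[[nm]])]
    out[[nm]] <- corpus[corpus$doc_id %in% take, ]
    at <- at + sizes[[nm]]
  }
  out
}
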