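# Per-type and TOTAL precision / recall / F1, token-level by default.
#
# A token with gold type g and prediction p contributes a true positive to g
# when p == g, otherwise a false negative to g and (when p is a trigger
# label) a false positive to p. TOTAL is micro-averaged over summed counts —
# the convention the published result tables follow. Percent scale, half-up
# rounding to two decimals.

#' Token-level confusion counts per trigger type
#'
#' @param gold,pred aligned character vectors of gold and predicted tags
#' @param labels the [label_set] (or character vector of trigger labels)
#' @param negative the negative tag (taken from the label set when one is
#'   given)
#' @return tibble with columns `type`, `tp`, `fp`, `fn`, one row per trigger
#'   type (the negative tag has no row)
#' @export
count_confusion <- function(gold, pred, labels, negative = "O") {
  if (length(gold) != length(pred)) {
    trignet_abort("count_confusion: gold and predicted tag vectors differ in length")
  }
  if (inherits(labels, "label_set")) {
    negative <- labels$negative
    labels <- labels$labels
  }
  tp <- fp <- fn <- stats::setNames(integer(length(labels)), labels)
  for (i in seq_along(gold)) {
    g <- gold[i]; p <- pred[i]
    if (g != negative) {
      if (identical(p, g)) tp[g] <- tp[g] + 1L else fn[g] <- fn[g] + 1L
    }
    if (p != negative && !identical(p, g) && p %in% labels) fp[p] <- fp[p] + 1L
  }
  tibble::tibble(type = labels, tp = unname(tp), fp = unname(fp), fn = unname(fn))
}

prf <- function(tp, fp, fn) {
  p <- ifelse(tp + fp == 0, 0, 100 * tp / (tp + fp))
  r <- ifelse(tp + fn == 0, 0, 100 * tp / (tp + fn))
  f <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  list(p = p, r = r, f = f)
}

#' Precision / recall / F1 report from confusion counts
#'
#' Per-type rows from each type's own counts, plus a `TOTAL` row
#' micro-averaged from the summed counts. All three measures are 0 when
#' their denominators are 0. Percent scale, rounded half-up to `digits`
#' decimals.
#'
#' @param counts a [count_confusion()] tibble
#' @param digits decimals for display rounding
#' @return tibble of class `trig_metrics` with columns `type`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`
#' @export
compute_metrics <- function(counts, digits = 2) {
  tot <- tibble::tibble(type = "TOTAL", tp = sum(counts$tp),
                        fp = sum(counts$fp), fn = sum(counts$fn))
  all <- dplyr::bind_rows(counts, tot)
  m <- prf(all$tp, all$fp, all$fn)
  all$precision <- round_half_up(m$p, digits)
  all$recall <- round_half_up(m$r, digits)
  all$f1 <- round_half_up(m$f, digits)
  class(all) <- c("trig_metrics", class(all))
  all
}

#' F1 from a precision / recall pair
#'
#' The harmonic mean on the percent scale with half-up display rounding;
#' 0 when `precision + recall == 0`. Reproduces the published TOTAL rows
#' from their printed precision and recall.
#'
#' @param precision,recall percent-scale values
#' @param digits decimals for display rounding
#' @return F1 on the percent scale
#' @examples
#' f1_measure(83.31, 79.40) # 81.31
#' @export
f1_measure <- function(precision, recall, digits = 2) {
  f <- ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
  round_half_up(f, digits)
}

#' Per-type and TOTAL metric deltas between two runs
#'
#' @param report_a,report_b [compute_metrics()] reports over the same label
#'   inventory (`b - a` on the percent scale)
#' @param digits decimals for display rounding
#' @return tibble with columns `type`, `d_precision`, `d_recall`, `d_f1`
#' @export
compare_runs <- function(report_a, report_b, digits = 2) {
  if (!setequal(report_a$type, report_b$type)) {
    trignet_abort("compare_runs: reports have different label inventories")
  }
  j <- dplyr::inner_join(report_a, report_b, by = "type",
                         suffix = c("_a", "_b"))
  tibble::tibble(
    type = j$type,
    d_precision = round_half_up(j$precision_b - j$precision_a, digits),
    d_recall = round_half_up(j$recall_b - j$recall_a, digits),
    d_f1 = round_half_up(j$f1_b - j$f1_a, digits)
  )
}

#' Evaluate a model on a gold corpus
#'
#' Tags the corpus and computes the token-level metrics report.
#'
#' @param model a `trignet_model`
#' @param corpus gold-tagged corpus tibble
#' @return a [compute_metrics()] report
#' @export
evaluate_model <- function(model, corpus) {
  pred <- predict_tags(model, corpus)
  compute_metrics(count_confusion(corpus$tag, pred$.pred, model$labels))
}

#' Span-level confusion counts
#'
#' Optional stricter mode for standoff outputs: a predicted span counts as a
#' true positive only with exact boundaries and type. Spans are maximal runs
#' of adjacent same-type tokens, mirroring [corpus_to_standoff()].
#'
#' @param gold_corpus,pred_corpus corpora aligned token-for-token;
#'   predictions in `pred_corpus$.pred`
#' @param labels the [label_set]
#' @return tibble as in [count_confusion()]
#' @export
count_confusion_spans <- function(gold_corpus, pred_corpus, labels) {
  negative <- labels$negative
  spans_of <- function(corpus, col) {
    sents <- corpus_sentences(corpus)
    out <- list()
    for (k in seq_along(sents)) {
      s <- sents[[k]]
      v <- ifelse(s[[col]] == negative, NA_character_, s[[col]])
      pos <- seq_len(nrow(s))
      sp <- span_collect(v, pos, pos) # inclusive ends: adjacent = +1 apart
      for (x in sp) {
        out[[length(out) + 1L]] <- paste(k, x$start, x$end, x$type, sep = "|")
      }
    }
    unlist(out) %||% character()
  }
  g <- spans_of(gold_corpus, "tag")
  p <- spans_of(pred_corpus, ".pred")
  type_of <- function(x) sub("^.*\\|", "", x)
  tibble::tibble(
    type = labels$labels,
    tp = vapply(labels$labels, function(l) sum(type_of(intersect(g, p)) == l), 0L,
                USE.NAMES = FALSE),
    fp = vapply(labels$labels, function(l) sum(type_of(setdiff(p, g)) == l), 0L,
                USE.NAMES = FALSE),
    fn = vapply(labels$labels, function(l) sum(type_of(setdiff(g, p)) == l), 0L,
                USE.NAMES = FALSE)
  )
}

#' Write a metrics report as TSV or JSON
#'
#' @param report a [compute_metrics()] report
#' @param path output file; extension `.json` selects JSON, anything else TSV
#' @return `path`, invisibly
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
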