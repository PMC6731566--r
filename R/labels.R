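# Label sets, overlap partitions, and the published trigger inventories of the
# three BioNLP corpora the transfer setting is built around.

#' Construct a trigger label set
#'
#' A label set is the ordered inventory of trigger (event) types of one
#' annotation domain, plus the negative tag assigned to tokens that trigger no
#' event. The negative tag is part of the tag inventory the tagger predicts
#' over but is never a trigger label.
#'
#' @param labels character vector of trigger-type names (unique, non-empty)
#' @param negative the no-event tag (default `"O"`); must not appear in
#'   `labels`
#' @return an object of class `label_set`
#' @examples
#' ls <- label_set(c("Phosphorylation", "Binding"))
#' n_tags(ls) # 3: two trigger types plus the negative tag
#' @export
label_set <- function(labels, negative = "O") {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) trignet_abort("labels must be unique")
  if (any(!nzchar(labels))) trignet_abort("labels must be non-empty strings")
  if (negative %in% labels) trignet_abort("negative label must not be a trigger label")
  structure(list(labels = labels, negative = negative), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("<label_set> ", length(x$labels), " trigger types + negative '",
      x$negative, "'\n", sep = "")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of tags in a label set
#'
#' Trigger types plus the negative tag; this is the size of the CRF tag
#' inventory (20 for the multi-level corpus: 19 event types + negative).
#'
#' @param x a [label_set]
#' @return integer tag count
#' @export
n_tags <- function(x) {
  stopifnot(inherits(x, "label_set"))
  length(x$labels) + 1L
}

# Full tag inventory in model order: negative first, then trigger labels.
tag_inventory <- function(x) c(x$negative, x$labels)

as_label_vector <- function(x) {
  if (inherits(x, "label_set")) x$labels else as.character(x)
}

#' Trigger label overlap between two domains
#'
#' Partitions the union of the source and target trigger inventories into the
#' shared labels (present in both), source-only and target-only labels.
#' Negative tags are never counted. The shared set drives how many
#' label-projection rows a generalized transfer plan can copy between domains.
#'
#' @param source,target [label_set] objects or character vectors of trigger
#'   labels
#' @return an object of class `label_overlap` with elements `shared`,
#'   `source_only`, `target_only`
#' @examples
#' ov <- compute_label_overlap(st09_label_set(), mlee_label_set())
#' length(ov$shared) # 9
#' @export
compute_label_overlap <- function(source, target) {
  s <- as_label_vector(source)
  t <- as_label_vector(target)
  structure(
    list(
      shared = intersect(s, t),
      source_only = setdiff(s, t),
      target_only = setdiff(t, s)
    ),
    class = "label_overlap"
  )
}

#' @export
print.label_overlap <- function(x, ...) {
  cat("<label_overlap> shared:", length(x$shared),
      " source-only:", length(x$source_only),
      " target-only:", length(x$target_only), "\n")
  if (length(x$shared)) cat("  shared:", paste(x$shared, collapse = ", "), "\n")
  invisible(x)
}

#' Published trigger inventories of the MLEE, BioNLP'09 ST and BioNLP'11 EPI corpora
#'
#' The trigger-type inventories as printed in the corpus descriptions:
#' 19 multi-level event types for MLEE, 9 molecular-level types for the
#' BioNLP'09 Shared Task corpus, and 15 protein-modification types for the
#' BioNLP'11 EPI corpus. Names use the corpora's canonical underscore form.
#' Nine MLEE types coincide with the ST'09 inventory and two with the EPI'11
#' inventory, which is the overlap structure the transfer models exploit.
#'
#' @return a [label_set]
#' @export
mlee_label_set <- function() {
  label_set(c(
    "Cell_proliferation", "Development", "Blood_vessel_development",
    "Growth", "Death", "Breakdown", "Remodeling",
    "Synthesis", "Gene_expression", "Transcription", "Protein_catabolism",
    "Phosphorylation", "Dephosphorylation",
    "Localization", "Binding", "Regulation",
    "Positive_regulation", "Negative_regulation", "Planned_process"
  ))
}

#' @rdname mlee_label_set
#' @export
st09_label_set <- function() {
  label_set(c(
    "Gene_expression", "Transcription", "Binding", "Protein_catabolism",
    "Phosphorylation", "Localization", "Regulation",
    "Positive_regulation", "Negative_regulation"
  ))
}

#' @rdname mlee_label_set
#' @export
epi11_label_set <- function() {
  label_set(c(
    "Hydroxylation", "Dehydroxylation", "Phosphorylation", "Deglycosylation",
    "Dephosphorylation", "Catalysis", "Ubiquitination", "Acetylation",
    "Deubiquitination", "DNA_methylation", "DNA_demethylation",
    "Glycosylation", "Deacetylation", "Methylation", "Demethylation"
  ))
}

#' Published document counts of the three corpora
#'
#' Abstract counts as printed in the corpus statistics tables: 262 for MLEE
#' (131 training + 44 development + 87 test), 950 for the BioNLP'09 ST
#' training+development combination and 800 for BioNLP'11 EPI. Used for
#' source/target size-ratio arithmetic.
#'
#' @return a tibble with columns `corpus` and `documents`
#' @export
bionlp_corpus_sizes <- function() {
  tibble::tibble(
    corpus = c("mlee", "st09", "epi11"),
    documents = c(262L, 950L, 800L)
  )
}
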