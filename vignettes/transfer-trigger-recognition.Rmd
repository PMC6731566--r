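---
title: "Trigger recognition with vertically partitioned transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger recognition with vertically partitioned transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trignet)
```

## The task and the model

Trigger recognition assigns an event-type label to each token of a sentence
(or the negative tag `O`). `trignet` treats it as sequence labelling with a
BiLSTM-CRF:

1. **Embedding layer.** Each token is the concatenation of up to five
   channels, in fixed order: a word embedding, the final hidden state of a
   character-level LSTM (orthography), a POS-tag embedding, a named-entity
   type embedding, and a dependency-context word embedding. POS tags, entity
   types and dependency heads are *inputs* (columns of the corpus), not
   computed: which tagger or parser produced them is outside the model.
2. **BiLSTM layer.** Peephole LSTM cells — the input and forget gates read
   the previous cell state, the output gate reads the current one, with the
   peephole weights acting elementwise. A forward and a backward pass are
   concatenated, so every token representation sees the whole sentence. A
   config switch (`network_config(peephole = FALSE)`) gives the standard
   cell.
3. **Fully-connected block.** A ReLU hidden layer followed by a *linear*
   projection to one emission score per tag. The published description names
   a single fully-connected layer yet the transfer scheme addresses the
   upper layer's parameters row-by-row per label; we resolve this with the
   two-stage block, where the label projection is the part partitioned by
   label overlap. This is a design choice of this package, recorded here,
   not a claim about the original architecture.
4. **CRF layer.** A standard linear-chain CRF with START/STOP virtual
   states, trained by maximum likelihood (forward recursion in log space)
   and decoded by Viterbi with ties broken toward the lowest tag index. No
   BIO-style transition constraints are imposed — tags are raw types per
   token, and adjacent same-type tokens are merged into one span only when
   writing standoff output.

Training minimises the negative sequence log-likelihood with Adam,
mini-batches of sentences, inverted dropout before the BiLSTM and
fully-connected layers (training only), global-norm gradient clipping at 5,
and optional early stopping on development-set micro F1 with parameter
restore. All of it is plain R matrix code; the backward pass is checked
against central-difference numerical gradients in the test suite.

## The transfer scheme

Let the source domain be annotation-rich (molecular-level triggers, 9 types)
and the target annotation-poor (multi-level triggers, 19 types, 9 of them
shared). Classical layer-wise transfer either shares everything (needs
identical feature *and* label sets), shares embeddings+BiLSTM (variant B,
needs identical feature sets), or shares only domain-independent embedding
tables (variant C). The generalized scheme (variant D) splits every layer
*vertically*:

* embedding tables of domain-independent channels are shared (the entity
  channel is domain-dependent by default: its inventory and dimension differ
  between domains, 10 vs 50 at published settings);
* BiLSTM input-weight **rows** belonging to shared channels are shared,
  along with all recurrent, peephole and bias blocks (the hidden dimension
  is common); the entity-channel rows stay domain-specific;
* the fully-connected hidden block is shared, and the label-projection
  **rows** (and biases) of every shared label are shared. The negative tag
  exists in both inventories, so its projection row is treated as shared
  whenever the overlap is non-empty — without it the transferred network
  scores the majority class with random weights, which empirically wipes out
  most of the transferred signal;
* CRF transitions are never transferred (an experimental flag can share
  transitions between shared-label pairs, off by default).

When the label overlap is empty the shared part of the fully-connected layer
is empty, and variant D degenerates *exactly* to variant B (identical
features) or variant C (inconsistent features); these reductions are
asserted as tests.

Training is three-phase: fit the source network on a `source_ratio` fraction
of source documents (document-level subsampling; phase 1 uses a 10% source
dev split for early stopping by default); copy the shared blocks through the
plan's index maps (vocabulary rows match by symbol, projection rows by label
name); fine-tune everything on the target corpus (no freezing by default —
`freeze_shared = TRUE` keeps transferred blocks fixed). Two details matter
in practice and are deliberate choices of this package:

* when a transfer happens, the target vocabulary is built over the union of
  the target training corpus and the (subsampled) source corpus, so
  transferred embedding rows of source-only words remain addressable at
  prediction time;
* the transferred initialization itself competes in early stopping (the dev
  score is also computed before the first phase-3 epoch), and a separate
  `phase3_lr` fine-tuning rate can protect transferred knowledge from large
  early Adam steps.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `dim_word` | 200 | word-embedding dimension |
| `dim_char` | 100 | character-LSTM hidden size (channel dimension) |
| `dim_pos` | 50 | POS-embedding dimension |
| `dim_entity` | 10 (source) / 50 (target) | entity-type embedding; the domain-dependent channel |
| `dim_dep` | 300 | dependency-context word embedding |
| `hidden_size` | 300 | BiLSTM hidden size per direction |
| `fc_dim` | 600 | ReLU hidden width |
| `dropout` | 0.5 | before BiLSTM and FC layers, training only |
| `lr` | 1e-3 | Adam learning rate |
| `batch_size` | 16 | sentences per update |
| `clip` | 5 | global gradient-norm threshold |
| `source_ratio` | 1 | fraction of source documents in phase 1 |

The embedding dimensions, hidden sizes and dropout follow the published
configuration. The optimiser, learning rate, batch size, epochs and clipping
are not specified there; the defaults above are this package's choices and
every one is overridable. Uniform random initialization in
`[-init_range, init_range]` with `init_range = 0.05` by default; pre-trained
word2vec-format tables can overlay the word and dependency channels (frozen
by default, `freeze = FALSE` to fine-tune).

**Small-network regime.** The tests and the bundled experiments run at much
smaller dimensions (word 16, hidden 12, FC 16) so they complete on one CPU
in minutes. In that regime the defaults tuned for full-size networks are too
timid: we use `init_range = 0.2`–`0.5` and learning rates of 0.01–0.05,
chosen because smaller values leave tiny networks on a label-symmetric
plateau (the model learns *where* triggers are long before *which* type they
are, and escaping that saddle needs a stronger symmetry-breaking signal).
The experiment problem sizes — 240 source sentences, 50 target training
sentences, 100 development sentences, 5 training seeds — are the package's
standard study conditions for the synthetic transfer comparison.

## The synthetic testbed

No licensed corpus ships with the package; all learning behaviour is
demonstrated on a seeded generator (`generate_domain_pair()`) that emulates
the *statistical* structure of the real setting:

* paired domains whose trigger inventories overlap by construction, with
  **shared trigger lexicons for shared labels** (one union lexicon is built
  first) and domain-specific entity inventories;
* sentences of background words with 0–2 triggers placed at least five
  tokens apart (expected `trigger_rate` per sentence, 1.5 by default);
* an `ambiguity` fraction (0.3 by default) of trigger words whose label is
  decided by a marker word within two tokens — a tagger that only memorises
  a lexicon cannot resolve these, so context modelling is actually
  exercised; `oracle_tag()` inverts the construction exactly and serves as
  the learnability ceiling;
* deterministic POS/dependency columns derived from the token stream.

What generated data does *not* emulate: real biomedical vocabulary and
spelling variation, class imbalance beyond the configured rates, multi-token
triggers, document discourse structure. Passing tests therefore show the
algorithms are implemented correctly and that the transfer mechanism moves
information between domains under controlled overlap — not that any
particular F1 would be reached on MLEE-scale corpora.

## Numerical choices and degenerate inputs

* CRF computations run in log space; the forward recursion and Viterbi are
  property-tested against exhaustive path enumeration (length ≤ 5, ≤ 4
  tags) to 1e-8.
* Partitioned middle/output layers must agree with dense assembly to 1e-10;
  they are alternative *views* of the same computation, so training always
  uses the dense form.
* Viterbi ties break toward the lowest tag index; with all-zero parameters
  the model predicts the first tag (the negative tag, which is index 1).
* Precision, recall and F1 are all defined as 0 when their denominators are
  0; reports use percent scale with half-up rounding to two decimals.
* Empty sentences, empty corpora and tags outside the inventory raise
  classed errors; a token overlapping two triggers of different types is an
  annotation conflict (error by default, first-wins behind a flag).
* Multi-token triggers are tagged type-per-token (no BIO scheme); how the
  original experiments tagged them is not documented, and this is the
  simplest reading of a per-token tag sequence.

## Known limitations

* Pure-R training is slow at published dimensions; the package is built for
  method study and small-corpus experiments, not for full-scale training
  runs (which would want GPU kernels — out of scope).
* Token-level evaluation is the default; span-level (exact boundary + type)
  counting is provided but approximate-span matching of shared-task
  evaluators is not.
* Event argument structures (`E` lines in standoff) are not parsed; only
  entity (`.a1`) and trigger (`.a2`) `T` lines are consumed.
* Transfer of knowledge to trigger types absent from the source domain
  relies entirely on phase-3 training; rare target-only types with a
  handful of instances remain hard, which mirrors the published error
  analysis for rare types.
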