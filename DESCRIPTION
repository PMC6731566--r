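Package: trignet
Title: Biomedical Event Trigger Recognition with Cross-Domain Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Token-level recognition of biomedical event triggers with a
    BiLSTM-CRF sequence tagger (peephole LSTM cells, a ReLU fully-connected
    layer and a linear-chain CRF), and a generalized cross-domain transfer
    learning scheme that vertically partitions every layer's parameters into
    domain-shared and domain-specific blocks driven by the overlap of the
    source and target feature and label sets. Includes readers and writers for
    BioNLP standoff and CoNLL-style column corpora, micro-averaged per-type
    evaluation, a seeded synthetic corpus generator for paired source/target
    domains with controllable label overlap, three-phase transfer training
    with a tunable source-data ratio, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
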