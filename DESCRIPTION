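Package: tokenlattice
Title: Token Lattice Tokenization for Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tokenizes biomedical and clinical text (for example SNOMED CT style
    concept descriptions) with the token lattice design pattern. Finite token
    transducers propose candidate segmentations, a lattice constructor assembles
    them into a bounded directed acyclic lattice, and an adapted Viterbi decoder
    over a part-of-speech hidden Markov model (order 0 or 1) selects the most
    likely tagged token sequence. Includes model training from slash-format
    tagged corpora, evaluation statistics (exact-match accuracy, normal
    approximation binomial confidence intervals, Cohen's kappa), a synthetic
    fixture generator for testing without licensed corpora, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
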