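Package: parsitopic
Title: Parsimonious Topic Models with BIC-Guided Structure Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sparse multinomial topic models in which each document
    activates only a subset of topics and each topic designates only a
    subset of vocabulary words as topic-specific, with all remaining words
    explained by a single corpus-wide shared distribution.  Model structure
    (topic switches, word switches, and the number of topics) is learned
    jointly with the parameters by a generalized EM algorithm that descends
    a customized Bayesian information criterion whose coding scheme gives a
    specially cheap description length to words that are uninformative
    under every topic.  Includes top-down model-order selection, held-out
    document-completion likelihood, label purity and multi-label
    precision/recall evaluation, and a synthetic-corpus generator with
    planted structure for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
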