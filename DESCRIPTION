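Package: schemabind
Title: Role-Filler Binding in Recurrent Networks with External Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying whether recurrent
    neural networks learn role-filler binding from schema-generated stories.
    Provides a stochastic story generator over event-schema graphs (the
    "coffee shop world"), random unit-norm word embeddings with optional
    distributional structure on filler vectors, four recurrent architectures
    (layer-normalized RNN, LSTM, Fast Weights, and a Differentiable Neural
    Computer) trained by backpropagation through time to retrieve the
    target filler embedding, cosine-similarity retrieval
    evaluation, ridge-regression decoding of fillers from hidden states and
    external memory, read/write-weight analyses of the memory buffer, and
    correlation-violation, correlation-retention, ambiguous-query, and
    shuffled-story probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
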