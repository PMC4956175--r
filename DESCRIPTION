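Package: edrconnectome
Title: Exponential Distance Rule Models and Comparative Statistics for
    Interareal Cortical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models of interareal cortical connectomes based on the
    exponential distance rule (EDR), in which the probability of an axonal
    projection of length d decays as exp(-lambda * d), together with the
    constant distance rule (CDR) null model. Provides decay-rate estimation
    from projection-length data, model fitting by parameter matching of
    network statistics, directed 3-node motif censuses with degree-preserving
    rewiring nulls, clique censuses and clique-based core-periphery
    extraction, chance-corrected connection-similarity profiles, total
    wire-length statistics with yoked-permutation nulls and simulated
    annealing placement optimization, and a synthetic-species generator that
    emulates the geometry and statistics of real tract-tracing datasets on a
    common adimensional spatial template.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
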