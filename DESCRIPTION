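Package: fertsig
Title: Evolution of Fertility-Linked Chemical Signals on Phylogenies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the evolutionary origin of queen pheromones and
    fertility-linked cuticular compounds in bees. Converts per-caste chemical
    profiles (queen versus worker, or mature versus virgin female) into a
    binary species-by-compound-class character matrix, reconstructs ancestral
    states on a fixed rooted phylogeny by maximum likelihood under the
    symmetric one-parameter Markov (Mk1) model with the Felsenstein pruning
    algorithm, reports marginal (proportional) likelihoods of presence at
    named clades, and paints branches exceeding a likelihood threshold.
    Includes simulators for Yule trees, binary characters evolving under the
    same Markov process, and caste chemical-profile tables with known ground
    truth, plus brute-force reference implementations used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
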