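Package: inteinkit
Title: Phylogenetic Dynamics of Neighboring Inteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the gain and loss of neighboring inteins (self-splicing
    mobile protein elements) on a phylogeny with constrained four-state
    continuous-time Markov models, contrasting a model in which two adjacent
    insertion sites can only be invaded or lost one at a time against a model
    that additionally allows simultaneous double invasion ("co-homing").
    Provides maximum-likelihood fitting with AICc model comparison, minimal
    ancestor deviation (MAD) rooting, intein co-occurrence statistics under
    independence, insertion-site flank profiling from annotated protein
    alignments, PSSM-based intein and homing-endonuclease detection in
    proteomes, and a synthetic-data generator with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    jsonlite,
    phytools,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
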