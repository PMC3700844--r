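Package: ogsim
Title: Forward-Time Population Genetic Simulation with Operation-Graph
    Genotype Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A neutral forward-time population genetic simulator (Wright-Fisher
    and Moran reproduction) whose genotype storage is losslessly compressed
    through an operation graph: a rooted, weighted directed acyclic graph in
    which every node records one evolutionary event (point mutation, insertion,
    deletion, crossover, or regulatory binding-site gain/loss) and a genotype
    is reconstructed on demand by replaying events down from a small set of
    explicitly stored ancestors.  The Greedy-Load cache policy keeps the number
    of explicit genotypes below a user-set budget k while tracking the
    decompression demand ("load") of the population, so that memory stays
    bounded and per-generation run time stays near-constant.  Store-Active and
    Store-Root baseline policies, partial (per-base) and batch decompression,
    parameter rescaling, per-generation instrumentation, and population-genetic
    verification statistics (Watterson's theta, nucleotide diversity) are
    included, for both DNA-sequence and regulatory-pathway genotype models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
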