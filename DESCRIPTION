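Package: fcgrvec
Title: Alignment-Free Genome Comparison via Chaos Game Representation
    Spectral Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts nucleotide sequences into short numeric vectors by
    tallying k-mer frequencies as Frequency Chaos Game Representation
    (FCGR) images, truncating their low-frequency DCT-IV spectrum, and
    embedding the flattened coefficients with a truncated singular value
    decomposition. The resulting vectors support exact kd-tree
    nearest-neighbor taxonomy lookup, majority-vote genome
    classification, phage-host consensus prediction, distance-based
    hierarchical phylogenetic trees, classical multidimensional scaling,
    and Robinson-Foulds tree comparison. Includes a seeded hierarchical
    Markov-chain sequence simulator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'fcgrvec-package.R'
    'benchmark.R'
    'classify.R'
    'cli.R'
    'embedding.R'
    'fcgr.R'
    'phylo.R'
    'pipeline.R'
    'seqio.R'
    'spectral.R'
    'synth.R'
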