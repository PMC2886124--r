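Package: orfdecay
Title: Pseudogene Evolution: ORF-Disruption Mapping, Codon Models, and
    Neutral Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the pseudogenization of protein-coding
    genes on a phylogeny. Detects open-reading-frame disruptions
    (frameshifting indels and premature stop codons), maps them to tree
    branches under Dollo parsimony and classifies lineages as intact,
    founding-pseudogene or inherited-pseudogene. Fits Goldman-Yang codon
    substitution models by maximum likelihood (branch models with labelled
    omega classes, site models M0/M1a/M2a/M3/M7/M8, branch-site model A,
    free-ratio), performs likelihood-ratio tests and naive empirical Bayes
    site posteriors, estimates the neutral ORF-disruption rate with Poisson
    uncertainty, simulates neutral ORF decay to compute the probability of
    keeping an intact frame, and tests correlated gene loss between
    paralogs. Includes a synthetic codon-evolution generator so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    Matrix,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
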