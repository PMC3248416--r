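Package: mechcodon
Title: Mechanistic Codon Substitution Models with Multiple Nucleotide
    Changes and Selective Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-reversible codon substitution models for phylogenetic
    analysis of protein-coding sequences.  A mechanistic model family
    combines a GTR-style nucleotide mutation process, multiple nucleotide
    changes in infinitesimal time, and amino-acid-level selective
    constraints tailored to a gene as a linear function of a given
    constraint estimate.  Empirical amino acid and empirical codon
    exchangeability matrices can also be converted into codon models.
    Site heterogeneity in mutation rate or in selective constraint is
    handled by discrete-gamma mixtures, and rate variation over time by a
    closed-form gamma expectation of the transition matrix.  Likelihoods
    are computed by Felsenstein pruning on fixed topologies, with ML
    optimization of branch lengths and model parameters, AIC/BIC/LRT
    model comparison, per-site posterior constraint summaries, and a
    seeded sequence simulator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phangorn,
    Biostrings
Config/testthat/edition: 3
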