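Package: phagering
Title: Discovery and Characterization of Complete Phage Genomes from
    Metagenome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for recovering complete phage genomes
    from whole-community gut metagenome assemblies and characterizing them.
    Candidate genomes are recognized as "circular" contigs carrying a direct
    terminal repeat, screened with phage hallmark-gene profiles (terminase
    large subunit, major capsid protein, portal) under a two-round e-value
    scheme that accommodates amber (TAG to glutamine) codon reassignment,
    and dereplicated at 95% average nucleotide identity over 80% of the
    genome length. Downstream characterization covers CRISPR spacer to
    protospacer host prediction, anti-CRISPR candidate screening by genomic
    context, detection of diversity-generating retroelements with a binomial
    test for their adenine-specific substitution hallmark, profile-profile
    marker clustering with a UPGMA guide dendrogram, hypergeometric
    gene-sharing networks, and length-normalized fractional abundance
    profiling from virome reads. A synthetic-community generator with full
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
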