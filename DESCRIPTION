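Package: arsafam
Title: Phylogenetic Congruence and Genome-Context Analysis of ArsA ATPase Homologues
Version: 0.1.0
Authors@R:
    person("Rook", "Castile", email = "rcastile@example.org", role = c("aut", "cre"))
Description: Tools for comparative-genomics analysis of the ArsA ATPase family
    and the membrane transporters it is proposed to energize (ArsB, Acr3, ArsP,
    CstA). Provides a curated catalog of 212 ArsA homologues in 18 phylogenetic
    clusters with per-cluster size summaries; redundancy and fragment filtering
    of protein sets at a percent-identity cutoff; affine-gap global and
    progressive multiple alignment with BLOSUM62; neighbor-joining tree
    construction with Newick round-tripping; a permutation-based tree-congruence
    (coevolution) test combining Robinson-Foulds and cophenetic-correlation
    statistics over operon-restricted protein pairings; operon delineation and
    genome-context association profiling from annotation tables; ungapped EM
    (OOPS) motif discovery with conservation reporting; Kyte-Doolittle
    hydropathy profiling with simple transmembrane-segment calling; and seeded
    simulators for coevolving protein family pairs and operon-structured
    genomes so the whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
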