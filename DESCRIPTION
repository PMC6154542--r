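Package: scotdiv
Title: Sampling-Size Optimization and Diversity Analysis for Dominant
    Molecular Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding how many individuals to sample from a
    population when genetic diversity is assayed with dominant
    presence/absence markers (SCoT, ISSR, RAPD, AFLP band profiles).
    Provides a validated band-matrix data model with delimited-text I/O;
    pooled band-as-allele diversity statistics (observed band number,
    percentage of polymorphic bands, expected heterozygosity, polymorphism
    information content, Shannon index, primer resolving power); random
    subsampling retention curves with an exact hypergeometric rarefaction
    expectation and plateau detection; one-level AMOVA with Phi-ST and
    permutation testing; Jaccard/UPGMA clustering with band-bootstrap clade
    support and Newick export; a lightweight Gibbs-sampled admixture model
    with Evanno delta-K selection of the number of clusters; and a
    synthetic band-matrix generator with recorded ground truth for testing
    the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
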