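Package: phylodisc
Title: Diagnosing the Sources of Gene-Tree Discordance and Selecting
    Clock-Like Loci for Divergence Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogenomic discordance analysis in the spirit of
    triplet-based introgression tests. Fits two competing models to the
    internal branch lengths of species triplets extracted from gene trees
    (an exponential incomplete-lineage-sorting model and an
    exponential-plus-shifted-exponential mixture adding an introgression
    component), selects between them by BIC, and summarises significant
    triplets into introgression and ILS events. Also provides per-locus
    concordance and clock metrics with a "gene shopping" tercile
    stratification for divergence dating, quartet concordance scores,
    reverse-constraint partitioned Bremer support under Fitch parsimony,
    k-mer/neighbour-joining orthology clustering with alignment
    masking/trimming, and a multispecies-coalescent simulator with
    introgression pulses and molecular-rate heterogeneity that generates
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
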