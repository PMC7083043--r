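Package: snpanel
Title: Cross-Species SNP Panels, Diagnostic Markers and Phylogenies from
    Pileup Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds non-redundant, missing-data-free SNP genotype matrices
    for panels of selfing diploid species genotyped against a single
    reference genome, starting from per-site pileup base counts.  Implements
    threshold-based homozygous variant calling (minimum depth, strict
    majority allele fraction), classification of sites as within-species
    polymorphic, between-species fixed, or genome-unique, pairwise
    nucleotide-difference diversity summaries, neighbor-joining trees with
    column bootstrap and outgroup rooting, congruence analysis of nuclear
    versus organellar partitions, and conversion of fixed SNPs into CAPS
    (cleaved amplified polymorphic sequence) restriction markers.  A
    panel simulator with Jukes-Cantor evolution along a configurable
    species tree, Poisson or negative-binomial coverage, dropouts and
    per-read error provides fully known truth sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
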