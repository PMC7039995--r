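Package: hlapop
Title: Population Immunogenetics of HLA Blocks and Conserved Extended Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level analysis of human leukocyte antigen
    (HLA) genotype data: allele nomenclature parsing and resolution handling,
    haplotype frequency estimation by family segregation counting and
    expectation-maximization, two-locus and block-level linkage disequilibrium
    (delta, Lewontin's standardized delta-prime, and a sample-size adjusted t
    statistic), conserved extended haplotype scans, per-locus diversity
    metrics (observed/expected heterozygosity, Monte-Carlo Hardy-Weinberg
    tests, polymorphism information content, power of discrimination),
    rule-based most-probable-ancestry assignment with aggregate block
    frequencies, a permutation test for non-overlapping allele associations
    between loci, cross-population analyses (Nei's DA distance,
    neighbor-joining trees with bootstrap support, principal components), and
    regressions of HLA diversity on distance-from-Africa and pathogen
    richness. A synthetic diploid cohort generator with configurable
    inbreeding, family trios and ancestry-labelled haplotype pools supports
    fully reproducible testing without any external genotype download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
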