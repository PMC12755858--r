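Package: xstrlink
Title: Linkage and Recombination Analysis of X-Chromosomal STR Linkage Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the linkage and recombination behaviour of
    X-chromosomal short tandem repeat (X-STR) linkage groups, as used in forensic
    kinship analysis. Implements a trio-based method that traces the maternal
    haplotype-of-origin of the chromosomal segments flanking each target locus
    from phased SNP data and estimates recombination fractions between linkage
    groups; phase-marginalised maximum-likelihood two-point linkage (MLOD) with
    the Kosambi mapping function for two-generation STR families; pairwise
    linkage-disequilibrium statistics (D, D', r-squared) and distance-binned LD
    decay curves on phased haplotypes; exact Clopper-Pearson binomial intervals
    and Fisher's exact test; and a meiosis simulator that generates phased trio
    cohorts and STR family tables with known crossover truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
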