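Package: selfmeth
Title: Genetic Diversity, DNA Methylation and Parasite Load Analysis for
    Mixed-Mating Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for population-level studies linking genetic
    diversity, genome-wide DNA methylation and parasite pressure in
    mixed-mating (selfing/outcrossing) organisms. Provides readers and
    validators for codominant microsatellite genotype tables,
    methylation-sensitive AFLP (MS-AFLP) dual-digest band matrices, parasite
    count tables and cluster-membership (q-value) matrices; scoring of
    HpaII/MspI band patterns into methylation states with classification of
    loci into methylation-susceptible and non-methylated classes; diversity
    statistics (Na, Ho, He, FIS), homozygosity-by-locus, equilibrium
    selfing-rate estimation and q-threshold classification of selfed versus
    outcrossed individuals; one-level AMOVA with Phi-statistics and
    permutation tests, pairwise Phi, principal coordinates analysis and
    Mantel tests; scaled parasite loads, prevalence and rank-based group
    comparisons; binomial GLMs of per-individual methylation proportion with
    exhaustive candidate enumeration and AICc-based multimodel comparison;
    and a forward-in-time mixed-mating population simulator that generates
    complete synthetic datasets with a truth record for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
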