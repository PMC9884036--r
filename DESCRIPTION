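Package: archipop
Title: Dual-Marker Population Genetics for Island Archipelagos
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for joint mitochondrial-sequence and nuclear
    microsatellite population genetics of island-structured populations.
    Implements sequence diversity statistics (haplotype diversity, nucleotide
    diversity, Watterson's theta, Dxy), neutrality tests (Tajima's D, Fu's Fs
    via the Ewens sampling formula), haplotype networks, microsatellite
    diversity and equilibrium testing (exact HWE, genotypic LD, null-allele
    screening, hypergeometric rarefaction), Weir-Cockerham F-statistics with
    ENA null-allele correction, AMOVA, PCA/DAPC ordination, isolation-by-
    distance tests, sex-biased dispersal assignment indices, linkage-
    disequilibrium and mutation-model effective population size estimators,
    and the modified Garza-Williamson M-ratio with coalescent critical-M
    simulation. A forward-time island-model simulator with two-phase
    microsatellite mutation and maternal mitochondrial transmission provides
    synthetic datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    MASS,
    geosphere,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
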