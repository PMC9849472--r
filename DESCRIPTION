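Package: mtpopgen
Title: Mitochondrial DNA Population Genetics on Partial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic analysis of aligned human mitochondrial DNA
    restricted to configurable rCRS regions (HVS-I plus coding windows):
    rCRS-relative variant profiles, haplotype collapsing, molecular
    diversity indices (gene and nucleotide diversity, mean pairwise
    differences), Tajima's D and Fu's Fs neutrality tests with coalescent
    simulation p-values, AMOVA-based pairwise Fst with gene flow (M = Nem)
    and classical MDS, mismatch distributions with sudden-expansion model
    fitting (tau, theta0, theta1, SSD, Harpending's raggedness) and
    parametric-bootstrap p-values, median-joining haplotype networks,
    rho-statistic TMRCA dating with Saillard standard errors and a
    Gompertz-type purifying-selection clock correction, shared-haplogroup
    admixture partitioning, and a seeded coalescent simulator for
    constant-size, sudden-expansion and two-deme demographies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
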