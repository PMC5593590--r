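Package: popindel
Title: Forensic and Population Genetic Analysis of Biallelic InDel Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of diploid genotype panels of biallelic
    insertion/deletion (InDel) markers, as used in forensic population
    surveys: per-locus forensic efficiency parameters (observed and expected
    heterozygosity, match probability, powers of discrimination and
    exclusion, paternity index, polymorphic information content) with
    panel-level combined powers; exact and chi-square Hardy-Weinberg tests
    with Bonferroni correction; pairwise linkage-disequilibrium r-squared
    from EM haplotype frequencies; Weir-Cockerham Fst with permutation
    p-values and per-locus Fisher differentiation tests; Nei's DA genetic
    distance with neighbor-joining trees; individual- and population-level
    principal component analysis; a maximum-likelihood EM admixture model
    with cross-validated choice of the number of ancestral populations; and
    a Balding-Nichols simulator of multi-population genotype panels for
    calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
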