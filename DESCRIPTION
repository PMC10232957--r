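Package: agtscreen
Title: Screening Rice Germplasm for Anaerobic Germination Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for replicated screening trials of rice
    germplasm under early-stage submergence (anaerobic germination).
    Computes seedling vigor indices and tolerance/grain-type
    classifications, randomized-complete-block and pooled-over-seasons
    ANOVA with method-of-moments variance components, genetic
    variability parameters (GCV, PCV, broad-sense heritability, genetic
    advance), Newman-Keuls multiple-range comparisons with compact
    letter displays, Pearson correlation, correlation-matrix principal
    component analysis, Gower distance with Ward.D2 clustering, and
    SSR/InDel marker diversity (allele counts, major allele frequency,
    polymorphic information content), marker-based distances and
    single-marker trait association. Includes seeded simulators for
    multi-environment trials, binomial germination counts and
    multi-allelic marker panels so every stage is testable end to end,
    plus the pooled genotype-mean table of a 119-genotype landrace
    screening panel as a packaged example dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
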