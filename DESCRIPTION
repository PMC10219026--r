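Package: snptata
Title: Promoter SNP Effects on TATA-Binding Protein Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates equilibrium dissociation constants (Kd) of the
    TATA-binding protein (TBP) for proximal promoter sequences with a
    three-stage binding model (sliding along the helix, stopping at a
    TATA-like site, bending of the DNA), compares ancestral and minor SNP
    alleles with a Fisher Z statistic, classifies candidate regulatory SNP
    markers by predicted expression direction and health effect, and runs
    the downstream selection-mode statistics: exact directional binomial
    tests with Bonferroni correction, phylostratigraphic age summaries over
    Venn-partitioned gene sets, Mann-Whitney comparisons, and concordance
    tests against domestic-versus-wild differential-expression tables. A
    seeded synthetic-data generator emits promoters with embedded TATA
    boxes of tunable strength, SNP sets with known expected effect
    directions, gene annotation tables and DEG tables, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
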