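Package: pavpan
Title: Gene Presence/Absence Variation Genotyping and Pan-Genome Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coverage-based genotyping of gene presence/absence variation (PAV)
    from per-base depth tracks over CDS annotations, occupancy-based
    core/softcore/shell/cloud pan-genome classification with permutation
    saturation curves, and PAV-based population genetics: principal component
    analysis, p-distance and neighbour-joining trees, per-gene two-population
    fixation index (Weir-Cockerham and Hudson estimators) with an empirical
    top-fraction scan, and binary-marker association between gene content and a
    wild-versus-selection phenotype via general linear and EMMA-style mixed
    linear models with a Fisher-exact baseline. Includes a synthetic-cohort
    generator (Balding-Nichols differentiation, interval-wise Poisson depth)
    with full truth tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    ape,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
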