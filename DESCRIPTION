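Package: cagtract
Title: HTT CAG Repeat Structure, Somatic Expansion Scoring, and Onset-Modifier Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Huntington's disease HTT exon-1 repeat region:
    run-length models of the CAG tract and its triplet-repeat flank with
    canonical / CAA-loss / CAACAG-duplication classification, k-mer anchored
    profiling of paired-end sequencing reads into repeat structures and
    genotypes, a somatic-expansion "peak proportional sum" index computed from
    capillary fragment-analysis peak tables with per-plate size-to-CAG
    calibration, residual age-at-onset phenotyping with correction of
    fragment-assay CAG mis-estimates on non-canonical alleles, Hardy-Weinberg
    enrichment testing with an externally fixed allele frequency, marginal and
    conditional modifier association, a declarative tag-SNP rule engine, and
    seeded generators for synthetic cohorts, reads, and fragment traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
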