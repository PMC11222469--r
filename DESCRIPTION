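Package: depbias
Title: Scoring Lineage-Biased Dependencies from Domain-Focused CRISPR Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for the computational stages of a
    domain-focused CRISPR/Cas9 dropout screen and its downstream mechanistic
    assays. Demultiplexes stacking-barcoded amplicon reads, counts guides by
    exact protospacer match, computes per-gene Essentiality Scores and
    group-differential (lineage-biased) dependency rankings, applies the
    unique-peptide fold-enrichment rule to dual interactome experiments and
    intersects them, classifies chromatin loops as shared or gained by
    dual-anchor overlap with loop-length statistics, overlaps ChIP-seq peak
    sets, and normalizes competition-proliferation, drug-sensitization and
    DNA-fiber restart measurements. Seeded synthetic-data generators with
    planted ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
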