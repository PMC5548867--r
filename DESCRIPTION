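Package: qresplice
Title: Alternative Splicing Event Integration and QKI Response Element
    Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates skipped-exon calls from junction-count based splicing
    tools (rMATS-style tables) with differential exon usage results
    (DEXSeq-style tables) into stringent (intersection) and comprehensive
    (union) event sets, classifies exons as cassette, mixed or terminal from a
    GTF gene model, scans strand-aware intronic flanking windows for the QKI
    binding core ACUAA and the full bipartite QKI response element
    ACUAAY-(N1-20)-UAAY with mismatch tolerance, and tests motif enrichment
    against a coverage-matched non-alternatively-spliced control exon universe
    by resampling. A deterministic synthetic data generator emulates all
    pipeline inputs with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
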