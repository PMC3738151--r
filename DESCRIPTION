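Package: chiparbiter
Title: Arbitration of Disputed ChIP-chip Targets via Mode-Anchored
    Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-analysis toolkit for bacterial ChIP-chip tiling-array
    data. Estimates a null signal distribution anchored at the modal
    probe value (standard deviation fitted from sub-modal probes),
    converts probe signals to z-scores, calls binding-site targets with
    adjacent-probe suppression, arbitrates "disputed" targets between
    two studies run on different probe grids, classifies targets by
    genomic context (genic, intergenic, convergent gaps) with a binomial
    enrichment test, quantifies replicate concordance and dynamic range,
    compares disputed-target scores to random probes with a
    Mann-Whitney U test, and converts ChIP/qPCR Ct tables into
    background-subtracted occupancy units. A fully seeded synthetic-data
    generator emulates two studies x two replicates of tiling-array
    signal over an annotated genome so that every pipeline stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
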