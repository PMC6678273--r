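Package: phageCurate
Title: Evidence-Integration Scoring for Manual Phage Genome Annotation
Version: 0.1.0
Authors@R:
    person("phageCurate", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic decision engine for the manual curation of
    bacteriophage genome annotations. Enumerates open reading frames and
    candidate start codons, integrates five evidence sources (auto-annotation
    program consensus, coding-potential posteriors, sequence similarity,
    overlap/operon context, and ORF length) into an additive keep/discard
    rubric, applies an ordered elimination procedure to choose start codons,
    and benchmarks annotations against a reference with sensitivity,
    specificity and start-accuracy metrics. Includes a synthetic genome
    simulator with planted genes and mock evidence so the whole pipeline is
    testable without external gene callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
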