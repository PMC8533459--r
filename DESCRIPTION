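Package: lichenBGC
Title: Comparative Analysis of Biosynthetic Gene Clusters in Lichen Fungal Chemotypes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide comparison of the biosynthetic gene cluster (BGC)
    complements of two chemotypes of a lichen-forming fungus, and triage of
    the candidate depside/depsidone polyketide cluster. Implements
    reciprocal best-hit matching of cluster core genes across genomes,
    polyketide synthase (PKS) domain-architecture parsing and group
    placement against labelled references, a four-criterion candidate
    filter with per-cluster exclusion evidence, detection of the divergently
    transcribed HexA/HexB fatty acid synthase locus, RPKM transcription
    quantification with library-size calibration from published values, and
    a combinatorial rule model of orcinol depside and depsidone assembly.
    A synthetic two-genome fixture generator mirrors the published cluster
    tables so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
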