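Package: sexscan
Title: Sex-Determination Region Mapping from Cross Segregation, Read Depth,
    Gametolog Divergence and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the heterogametic sex-determination system (XY versus ZW)
    of a dioecious species from pseudo-testcross marker segregation in an F1
    family, maps X- and Y-specific regions from male/female read-depth tracks
    by sliding-window copy-number classification with two-resolution boundary
    refinement, estimates synonymous divergence (NG86 counting with
    Jukes-Cantor correction) between XY gametolog coding sequences, and ranks
    candidate sex-determining genes with a three-stage differential-expression
    filter cascade. A seeded synthetic-data generator reproduces the
    statistical structure of the underlying sequencing experiments (Mendelian
    pseudo-testcross genotypes, negative-binomial depth and expression counts,
    gametolog pairs at a target dS) so that every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
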