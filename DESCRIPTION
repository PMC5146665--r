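Package: orthowindow
Title: Comparable-Region Annotation and Quantification for Cross-Species RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds paired "comparable region" annotations from pairwise
    alignments of 1:1 orthologous transcripts by tiling each alignment into
    fixed-length windows, retaining windows with high identity and few gaps,
    and mapping them to genomic coordinates in both species. Genes whose
    per-window read-depth profiles are poorly correlated between species are
    excluded (with an exact sign-test rescue for consistent one-species-higher
    coverage), and robust-regression outlier windows are removed, so that
    between-species differential-abundance comparisons are restricted to
    regions quantified on equal footing. Includes union-mode fragment counting
    over the retained windows, TMM/CPM/FPKM normalization, fold-change and
    threshold filtering, validation statistics (Welch's t, exact sign test),
    a seed-reproducible synthetic-data generator for diverged ortholog pairs
    with coverage tracks and fragments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
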