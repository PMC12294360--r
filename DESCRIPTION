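Package: cubkit
Title: Codon Usage Bias Analysis for Coding Sequence Sets
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-gene and per-species codon usage statistics for sets of
    coding sequences: positional GC content, relative synonymous codon
    usage (RSCU), the effective number of codons (ENC, observed and
    expected from synonymous third-position GC), the codon adaptation
    index (CAI), the codon bias index (CBI) and the frequency of optimal
    codons (FOP). Includes mutation-versus-selection diagnostics
    (neutrality regression of GC12 on GC3, ENC-GC3 deviation ratios with
    a synonymous-permutation null, parity-rule-2 plots, CAI-ENC
    association), preferred-codon calling, a cross-species RSCU heatmap
    layout, and a synthetic CDS generator with controllable base
    composition and translational-selection strength for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
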