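Package: isletscreen
Title: Pooled In Vivo CRISPR Screen Analysis for Stem-Cell-Derived Islet
    Graft Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of pooled genome-wide CRISPR knockout screens read out
    by guide abundance in transplanted stem-cell-derived islet grafts under
    allogeneic immune attack. Provides a synthetic screen generator with
    engraftment bottlenecks and condition-dependent selection, guide count
    and library file IO including exact-match spacer counting from amplicon
    FASTQ, control-guide anchored normalization, a gene-level integrated
    log2 fold-change statistic with an empirical null built from
    non-targeting guides and Benjamini-Hochberg FDR, per-guide negative
    binomial condition fits, and thresholded cross-assay hit-set
    intersection with exact Venn-region accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    readr,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
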