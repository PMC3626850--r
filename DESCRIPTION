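Package: tucrtile
Title: Strand-Aware Tiling-Array Analysis of Transcribed Ultraconserved Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for strand-specific tiling-microarray profiling
    of transcribed ultraconserved regions (T-UCRs). Provides probe tiling
    design over UCR loci with flanking coverage, quantile normalization,
    window-3 median smoothing, transcript summarization and expression
    calling, fold-change/t-test differential-expression filtering for
    retinoic-acid treatment designs, host-gene correlation classification and
    anti-correlation screening, strand-reorientation clustering with
    hypergeometric annotation enrichment, and gene-list overlap analysis.
    Includes a synthetic probe-intensity generator with planted ground truth
    that emulates the 3-cell-line by treatment by 2-repeat study design, so
    the full pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
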