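Package: methmarker
Title: Methylation Marker Discovery Along the Colorectal
    Adenoma-Carcinoma Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying genes with gradually altered expression
    along the colorectal normal-adenoma-carcinoma sequence and for
    quantifying promoter DNA methylation from bisulfite amplicon
    sequencing reads. Implements tie-corrected Kendall rank correlation
    trend selection with pairwise pooled-variance t-tests and
    Benjamini-Hochberg correction, sliding-window CpG island prediction,
    affine-gap Smith-Waterman-Gotoh local alignment of bisulfite reads
    against converted amplicon references with a score-fraction read
    filter, per-CpG methylation calling and group comparison, interplate
    and reference-gene normalisation of miRNA qPCR Ct panels,
    semiquantitative immunohistochemistry Quick-scores, synthetic data
    generators with planted ground truth for every stage, and a
    configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
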