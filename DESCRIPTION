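Package: permscreen
Title: Permutation-FDR Differential Expression Screening and CRISPR Edit
    Design for Low-Replicate RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing transcriptome-wide off-target effects of
    CRISPR/Cas9 genome editing when only two RNA-seq replicates per
    condition are available. Implements per-gene two-sample T statistics,
    a balanced mixed-permutation null, false discovery rate estimation by
    comparing observed and permutation-averaged T-statistic exceedance
    spectra, and extraction of a deliberately liberal "putative" gene set
    whose pathway enrichment propagates enrichment present among the true
    differentially expressed genes. Includes read-depth equalization by
    without-replacement count subsampling, hypergeometric gene-set
    over-representation with an immune-pathway screening verdict, a seeded
    negative-binomial count simulator with planted effects for
    calibration, sgRNA protospacer/PAM scanning with Golden-Gate cloning
    oligo construction and homology-directed repair template assembly,
    and descriptive summaries (hierarchical clustering, Venn counts,
    delta-delta-Ct relative quantification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
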