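Package: lmsomics
Title: Multi-Omic Subtyping of Leiomyosarcoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to stratify leiomyosarcoma (LMS) tumors into a
    transcriptionally homogeneous (hLMS) and a heterogeneous (oLMS) subtype
    and to characterize the two groups across omics layers. Implements
    cross-platform microarray harmonization (reproducible-gene selection,
    quantile normalization, median re-centering), co-expression module
    detection by edge-betweenness communities, a nearest-centroid classifier
    under the 1 - Spearman correlation distance with threshold and Gaussian
    mixture assignment, clinical enrichment and Kaplan-Meier/log-rank
    survival comparison, miRNA differential expression and miRNA-mRNA
    anti-correlation network integration, copy-number penetrance and
    cytoband enrichment, somatic variant filtering with per-gene alteration
    summaries, tumor mutation burden, and mutational-signature refitting by
    non-negative least squares. A seeded synthetic-data generator emulating
    the statistical structure of each input allows the whole pipeline to be
    exercised and tested without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    mclust,
    survival,
    limma,
    edgeR,
    pracma,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
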