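Package: relapseEvo
Title: Clonal and Epigenetic Evolution Analysis for Paired Diagnosis-Relapse AML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how acute myeloid leukemia evolves between
    diagnosis and relapse. Classifies paired variant-allele-frequency data
    into gained/lost/stable mutation dynamics and patient-level clonal bins,
    compares relapse-free survival between clonally stable and unstable
    patients, builds fixed-width consensus ATAC-seq peak sets by iterative
    overlap removal, computes decay-weighted gene accessibility scores,
    performs paired differential accessibility, derives and applies a relapse
    chromatin signature, projects query cells onto a labeled healthy
    hematopoietic reference by latent semantic indexing with closest-normal
    k-nearest-neighbor classification, and identifies mitochondrial clones
    from single-cell heteroplasmy to test for convergent epigenetic
    evolution. Ships synthetic-data generators with planted ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    DESeq2,
    SummarizedExperiment,
    survival,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class
Config/testthat/edition: 3
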