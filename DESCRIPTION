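Package: rdnacn
Title: Ribosomal DNA Copy Number and Sequence Variation from Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates 45S ribosomal DNA copy number from sequencing
    coverage normalized to a catalog of single-copy exons, compares
    matched tumor-normal pairs with cohort-level loss tests, discovers
    exons whose copy number co-varies with rDNA loss (paired tests, FDR
    selection, hierarchical clustering, hypergeometric enrichment),
    calls single-nucleotide variants in the repeat against a consensus
    with shared/unique classification and allele-number statistics,
    quantifies droplet digital PCR assays with Poisson correction, and
    measures nucleolar region areas from fluorescence images. A
    synthetic-data generator with truth manifests supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
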