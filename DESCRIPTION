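Package: nicscreen
Title: Non-Invasive Chromosome Screening Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, copy-number calling and concordance analysis for
    validating non-invasive chromosome screening (NICS) of IVF embryos
    against trophectoderm-biopsy PGT-A and whole-embryo ploidy. Provides a
    synthetic trio-cohort generator (MALBAC-like amplified count data with
    GC bias, assay-specific overdispersion, mosaicism and maternal
    contamination of spent culture medium), a chromosome-level copy-number
    caller for 1 Mb binned low-coverage counts (CV quality control, GC and
    reference normalization, in-house circular binary segmentation, ploidy
    classification with mosaic and multiple-abnormal-chromosome categories),
    and a diagnostic-concordance engine (Wilson score intervals, Cohen's
    kappa, exact McNemar test, chromosome-set Venn partitions, embryo
    prioritization groups and secondary-validation reclassification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
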