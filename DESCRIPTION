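Package: metpool
Title: Quantification of Pooled In Vivo Barcoding Experiments for Metastatic Potential Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pooled xenograft barcoding experiments:
    assignment of sequencing reads to clonal DNA barcodes under an
    end-overlap coverage rule, estimation of absolute and relative
    organ-specific metastatic potential with bootstrap confidence
    intervals and penetrance, in-silico mixture construction and
    composition-corrected paired differential expression with
    empirical-Bayes moderated t-statistics, two-class genomic feature
    association, mini-pool CRISPR screen depletion scoring with
    upper-quartile normalization, and a forward simulator of pooled
    in vivo barcoding experiments with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
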