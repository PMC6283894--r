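Package: lactodim
Title: Sex-Dimorphism Analysis of Lactotroph Pituitary Tumor Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sex-related differences in lactotroph
    (prolactin-secreting) pituitary tumors. Implements median normalization of
    oligonucleotide array intensities with a negative-control detection
    threshold, two-group differential expression with a signed fold-change
    convention and a joint significance/magnitude filter, a per-chromosome
    enrichment statistic for deregulated genes, exact penalized least-squares
    copy-number segmentation with fixed gain/loss cutoffs, integration of
    recurrently gained regions with upregulated genes, group-stratified
    Pearson correlation panels, and cohort summary tables. A synthetic-data
    generator emulates the statistical structure of a 30-tumor cohort (20 men,
    10 women) so the whole pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
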