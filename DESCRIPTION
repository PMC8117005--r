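Package: fasmosaic
Title: Whole-Blood Screening for Somatic FAS Mutations in ALPS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Region-restricted somatic variant filtering from strand-resolved
    allele counts for detecting low allele-fraction mosaic FAS mutations in
    autoimmune lymphoproliferative syndrome (ALPS) from whole-blood amplicon
    sequencing. Implements the customised somatic filter chain (minimum VAF,
    minimum supporting reads, Fisher strand-bias test), germline/somatic
    classification by allele-fraction bands, an exact-binomial limit-of-detection
    model linking sequencing depth to the detectable double-negative T-cell
    (DNT) fraction, a synthetic mosaic-pileup generator with ground truth, and a
    sensitivity/specificity validation harness with bundled published fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    vcfR
Config/testthat/edition: 3
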