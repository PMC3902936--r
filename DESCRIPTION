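Package: remsig
Title: Drug-Response Signature Matching for Engineered Reversal of Chemoresistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-engineering analysis of cell-line drug response: classifies
    cell lines as resistant or sensitive per drug from log10 GI50 values,
    derives per-gene signed differential statistics (v), builds drug-specific
    resistance-minus-sensitive gene signatures (response engineering modules,
    REMs), tests candidate gene sets against a random-set chi-square null,
    and scores gene-induction signatures for anti-correlation with REMs to
    predict reversal of drug resistance. Includes a synthetic-data module
    with planted, recorded ground truth so every stage of the pipeline can
    be validated offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
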