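Package: iceatt
Title: Attachment-Site Usage, Excision, and Fitness Costs of Integrative
    and Conjugative Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and quantifies the use of secondary attachment sites by
    site-specific integrative and conjugative elements (ICEs) such as
    ICEBs1 of Bacillus subtilis.  Provides a structured model of the 17 bp
    attachment-site core (5 bp inverted-repeat arms flanking a 7 bp
    crossover spacer) with mismatch scoring, heteroduplex prediction and
    integration/excision bookkeeping; mismatch-tolerant genome scanning for
    candidate sites; sequence-logo information content over aligned site
    contexts; the qPCR relative-quantification chain from Cq values to
    excision frequencies, circle-to-empty-site ratios and integration
    ratios; and a deterministic plus stochastic competition model for the
    population-level fitness cost of carrying an element at a site from
    which it cannot excise.  Synthetic-data generators with exact ground
    truth make every analysis testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
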