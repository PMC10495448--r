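Package: tp53screen
Title: Detecting Hidden Biallelic TP53 Inactivation from Transcriptomic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based calling of TP53 DNA status (biallelic, monoallelic,
    wild-type) from mutation, copy-number and B-allele-frequency evidence; an
    expression-signature random-forest scorer with AUPRC-first model selection
    and a maximum-sensitivity cutoff to nominate cryptic biallelic samples
    among DNA-monoallelic multiple myeloma cases; percent-spliced-in (PSI,
    dPSI) quantification of aberrant TP53 splicing, p53 isoform-imbalance
    ratios and mechanism assignment; native Kaplan-Meier, log-rank and
    Mann-Whitney survival statistics; and a seeded synthetic-cohort generator
    that emulates the statistical structure of the study data so the whole
    pipeline is testable without controlled-access genomics data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
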