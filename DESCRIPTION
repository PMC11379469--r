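Package: cfdecon
Title: Reference-Based Methylation Deconvolution of Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the tissue composition of cell-free DNA (cfDNA) from
    region-level CpG methylation counts. Proportions are inferred by a
    coverage-weighted matrix factorization on the probability simplex that
    can refine the reference atlas and learn the methylation profiles of
    contributors missing from it. Includes construction of a marker-region
    atlas from per-CpG methylation calls (one-versus-all differential
    methylation, region extension, Fisher exact testing), a simulator for
    Dirichlet/binomial cfDNA mixtures and tumor-fraction dilution series,
    and evaluation utilities (Pearson, MSE, accuracy, Cohen's kappa,
    control-normalized tissue-of-origin calling, limit-of-detection scans).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
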