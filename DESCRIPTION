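Package: epifreq
Title: Methylation Pattern Frequency Estimation from Bisulphite Amplicon
    Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the true frequency distribution of CpG methylation
    patterns (epialleles) at a locus from bisulphite amplicon read counts.
    Observed pattern counts are modelled as a multinomial sample pushed
    through a Kronecker-product misclassification matrix built from the
    bisulphite non-conversion rate and per-site sequencing error rates.
    The underlying pattern distribution is recovered by maximising the
    constrained multinomial log-likelihood on the probability simplex via
    expectation-maximisation with likelihood-driven boundary refinement,
    and observed patterns whose estimated frequency is identically zero
    are called spurious.  Includes a read-level simulator with the same
    error structure, threshold-classifier evaluation (TPR/FPR curves),
    plain-text table input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
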