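Package: cabsig
Title: Correlation-Based Classification of Gene-Signature Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies samples as signature-high or signature-low from the
    Pearson correlation of their expression profile with group prototypes,
    the approach introduced for the whole-blood type I interferon signature
    in rheumatoid arthritis. Provides median/MAD expression filtering,
    prototype bootstrapping by hierarchical clustering, per-gene correlation
    indexes and group-level R_median profiling, the classical mean-expression
    signature score with a healthy-control 95 percent limit, paired
    before/after monitoring with an exact Wilcoxon signed-rank test, a
    latent-factor synthetic cohort generator with closed-form inter-gene
    correlation targets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
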