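Package: svtcomplete
Title: Gene Expression Matrix Completion by Singular Value Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts complete gene expression matrices from a sparse subset
    of measured "checkpoint" values by low-rank matrix completion. Implements
    the singular value thresholding (SVT) solver for nuclear-norm minimisation
    with the standard parameter heuristics and omega-error stopping rule,
    recovery-error metrics (Frobenius, spectral, omega), synthetic low-rank
    generators with additive Gaussian noise for robustness studies, and a
    downstream differential-expression concordance evaluation on recovered
    matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    limma,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
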