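Package: adsig
Title: Cross-Species Atopic-Dermatitis Gene-Signature Discovery and Severity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a cross-species atopic-dermatitis (AD) gene
    signature and scoring disease severity from skin transcriptomes. Implements
    TMM-normalized negative-binomial exact tests for mouse RNA-seq counts, the
    SAM permutation statistic with Storey q-values for human microarray
    log-intensities, FAIME rank-weighted single-sample pathway scores with
    cross-contrast concordance tests, direction-concordant ortholog
    intersection into a +1/-1 weighted signature, the AD-index severity score
    with SCORAD correlation and paired treatment-response tests, and a
    Venet-style resampling framework that benchmarks signatures against random
    draws from defined gene pools. A synthetic-study generator with known
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
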