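Package: methsmooth
Title: Smooth Covariate Effects and Regional Tests for Targeted Bisulfite
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-level modeling of targeted bisulfite sequencing data.
    Methylated read counts are described by a binomial varying-coefficient
    model in which the intercept and every covariate effect is a smooth
    function of genomic position, represented by penalized cubic B-splines.
    An experimental-error layer (false methylation and false non-methylation
    call rates) is handled by a smoothed EM algorithm whose M-step combines
    penalized iteratively reweighted least squares with restricted-likelihood
    smoothing-parameter selection. Standard errors come from the
    Louis/Oakes observed information, giving pointwise confidence bands for
    the effect curves and a region-wide Wald test whose chi-square reference
    uses effective degrees of freedom. A seeded simulator generates
    realistic regional count data with known truth for power, type-I-error
    and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
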