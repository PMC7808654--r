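Package: gecko
Title: Genetic and Environmental Covariance Estimation by
    Composite-Likelihood Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the genetic and environmental covariance (and
    correlation) between two complex traits from GWAS summary statistics
    (marginal z-scores and LD scores) under a bivariate linear mixed
    model.  A weighted composite likelihood over per-SNP marginal
    z-score distributions is maximized by an EM algorithm with a
    Newton-Raphson polish; sample overlap between the two studies is
    modeled through an intercept term, annotation-stratified genetic
    covariances are supported, and standard errors come from a block
    jackknife over contiguous SNP blocks.  Includes LD-score computation
    from PLINK reference panels, LDSC-style summary-statistics
    harmonization, and a simulation harness for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
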