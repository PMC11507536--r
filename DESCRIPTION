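Package: OinfoBias
Title: O-Information Estimation with Miller-Maddow Bias Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the O-information of systems of discrete (or
    quantile-discretized) variables, quantifies the finite-sample bias of
    the naive plug-in estimator by simulation, and applies an additive
    bias correction derived from the Miller-Maddow entropy estimator.
    Provides deterministic equal-count (quantile) binning, plug-in and
    bias-corrected entropy estimation over column subsets, generators for
    fully redundant, fully independent and fully synergistic variable
    triplets, a grid driver for bias-landscape simulation studies over
    sample size and bin count, and a scan mode that ranks all variable
    triplets of a tabular dataset by naive and bias-corrected
    O-information against a matched independent-triplet null benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'OinfoBias-package.R'
    'binning.R'
    'infotheory.R'
    'oinfo.R'
    'simulate.R'
    'scan.R'
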