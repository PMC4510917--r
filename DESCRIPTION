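Package: erpcluster
Title: Cluster-Based and Threshold-Free FWER Correction for Mass-Univariate ERP Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate two-sample testing of event-related potential (ERP)
    epochs over the full channel-by-time data space, with family-wise error rate
    (FWER) control by max-statistic resampling. Implements the three classical
    cluster statistics (height, extent, t-squared mass) on spatiotemporal
    connected components, threshold-free cluster enhancement (TFCE), and three
    null-estimation engines (permutation, pooled percentile bootstrap,
    mean-centred bootstrap-t), together with a Monte-Carlo simulation harness
    that estimates the realised type-1 FWER, agreement between techniques, and
    convergence over resampling iteration counts, and a synthetic ERP generator
    producing exchangeable null trials with realistic spatiotemporal correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
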