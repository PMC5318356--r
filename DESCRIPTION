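Package: mignet
Title: Pairwise and Bayesian Network Meta-Analysis of Migraine Prophylaxis Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evidence synthesis for networks of randomized trials of
    prophylactic migraine medications. Implements DerSimonian-Laird
    random-effects pairwise meta-analysis of mean differences and odds
    ratios, an arm-based Bayesian random-effects network meta-analysis
    fitted by an adaptive Metropolis-within-Gibbs sampler, league tables,
    rank probabilities and SUCRA scores with k-means clustering of
    interventions, node-splitting assessment of consistency between
    direct and indirect evidence, design-level Q decomposition with
    net-heat contribution matrices, comparison-adjusted funnel data with
    Egger regression, and a simulator of trial networks with known truth
    for calibration studies. Ships a transcription of the seven-treatment
    migraine prophylaxis evidence base used throughout the examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
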