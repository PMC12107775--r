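Package: ccvkit
Title: Chemical Characteristics Vectors for Untargeted LC-MS/MS Sample Comparison
Version: 0.1.0
Authors@R:
    person("ccvkit", "developers", email = "ccvkit@example.org", role = c("aut", "cre"))
Description: Builds fixed-length chemical characteristics vectors (CCVs) from
    probabilistic per-peak molecular fingerprint and compound class predictions
    of untargeted LC-MS/MS experiments: predictions are binarized at a
    probability threshold and averaged per sample, optionally within precursor
    m/z groups, yielding comparable sample representations alongside MS1
    presence/absence and log10-intensity matrices. Includes recursive feature
    elimination with fold-consistency aggregation (rfe1/rfe2), clustering
    validity indices (Calinski-Harabasz, Dunn, silhouette) computed against
    biome labels, cross-validated classification with trivial baselines,
    compound class ratio summaries with Wilcoxon rank-sum contrasts, a
    synthetic study generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
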