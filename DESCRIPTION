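Package: prer
Title: Pairwise Relative Expression Ranks over Protein Interaction Neighborhoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes each patient's protein expression profile as pairwise
    relative-rank features restricted to protein-protein interaction (PPI)
    network neighborhoods, where neighborhoods are sampled with second-order
    biased random walks. Provides the full downstream analysis: univariate
    Cox screening, random survival forest evaluation under repeated holdout
    with the concordance index, paired Wilcoxon signed-rank comparisons of
    feature representations with Benjamini-Hochberg correction, permutation
    feature importance aggregated to per-protein scores and rank differences,
    a network-propagation baseline representation, and a synthetic-data
    generator that plants pairwise-order survival signal for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
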