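Package: ecocycler
Title: Ecosystem Novelty, Change Points, and Adaptive-Cycle Phases from Food-Web Flows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies ecosystem novelty as the minimum dissimilarity of each
    projected year's food-web state to a historical baseline (Euclidean on
    biomasses, Hellinger on composition, cumulative per-species differences),
    detects statistically significant shifts in the mean of the novelty series
    by exact penalized least-squares segmentation with a minimum segment
    length, computes ecological network analysis indices (total system
    throughput, ascendency, development capacity, overhead) from annual flow
    matrices, and maps their smoothed trends onto adaptive-cycle phases
    (growth, collapse, reorganization), counting cycles per scenario. Includes
    a synthetic food-web ensemble generator emulating Ecopath-with-Ecosim
    style outputs under crossed climate, nutrient-load, and fishing scenarios,
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
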