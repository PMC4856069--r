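Package: morphoqtl
Title: Multivariate QTL Mapping of 3D Landmark Shape in Experimental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative genetics of geometric shape in a mouse-style
    backcross: generalized Procrustes analysis of 2D/3D landmark and
    semilandmark configurations, thin-plate-spline warping and bending-energy
    sliding of surface semilandmarks on triangulated meshes, simulated 2D
    flattening of 3D configurations, hidden-Markov genotype probabilities on a
    centimorgan map, multivariate multiple-QTL model search with Pillai-trace
    penalized LOD scores and permutation-derived penalties, Bayes credible
    intervals, QTL effect summaries in shape space, and QTL-based genetic
    covariance (G) matrix comparison (root Euclidean distance, g-max angle
    tests, Krzanowski common subspaces, multivariate heritability). Includes a
    synthetic-data generator emulating the backcross study design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
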