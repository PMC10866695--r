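Package: ecotip
Title: Empirical Stability Landscapes and Ecosystem Transition Potential
    for Tropical Tree Cover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting alternative stable states of tropical tree
    cover along climatic gradients and for mapping ecosystem transition
    potential. Implements per-pixel climate metrics (mean annual
    precipitation, maximum cumulative water deficit, dry-season length,
    dry-season temperature), per-pixel trend regressions with significance
    screening and extrapolation to 2050, empirical potential analysis
    (kernel-density stability landscapes with mode/antimode detection,
    critical-threshold and bistability-range extraction, sensitivity
    sweeps), rainfall-based stability classification, an additive
    transition-potential index combining warming trends, projected
    stability classes, drought events, road proximity and governance, and
    a simplified Lagrangian atmospheric moisture-tracking simulator with
    source-to-target flow aggregation. A synthetic-data module generates
    bimodal tree-cover fields, trended climate cubes, disturbance layers
    and moisture-tracking forcing with known ground truth, so the whole
    chain is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'grid.R'
    'climate-cube.R'
    'climate-metrics.R'
    'ecotip-package.R'
    'io.R'
    'metric-map.R'
    'moisture-tracking.R'
    'pipeline.R'
    'potential-analysis.R'
    'stability-classes.R'
    'synthetic-biome.R'
    'synthetic-climate.R'
    'synthetic-disturbance.R'
    'transition-potential.R'
    'trends.R'
LinkingTo:
    Rcpp
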