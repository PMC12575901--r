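Package: segmap
Title: Event Segmentation Agreement for Dynamic Choropleth Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-segmentation studies
    of animated choropleth maps. Generates Voronoi region maps and the value
    dynamics of three experimental designs (random piecewise-linear trends,
    an orthogonal trend-by-framing-by-color-scale factorial, and a
    spatial-pattern factorial with clustered or distributed change),
    simulates key-press response logs from a change-driven hazard model,
    computes scaled segmentation agreement (observed minus minimum over
    maximum minus minimum attainable correlation with the leave-one-out
    group norm), tests it against permutation nulls and cross-stimulus
    baselines, and fits factorial linear mixed models with average marginal
    effects of trend and Monte-Carlo power simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
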