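Package: protonarc
Title: Automated Multi-Criteria Planning for Discrete Proton Arc Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale automated treatment planning for intensity-modulated
    proton therapy (IMPT) and discrete proton arc therapy (PAT) on synthetic
    phantoms. Provides wish-list driven lexicographic multi-criteria robust
    spot-weight optimization with sparsity-induced spot selection, group-lasso
    energy-layer reduction for 36-field arcs, beam-angle optimization by group
    sparsification over equiangular candidates, monitor-unit feasibility
    finalization and plan normalization, and DVH/NTCP-based bias-free plan
    comparison with exact paired Wilcoxon signed-rank tests. Dose is computed
    with a simplified analytic pencil-beam model (parametric Bragg curve with
    depth-growing Gaussian penumbra) over a 21-scenario setup/range robustness
    set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
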