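Package: fissim
Title: Dynamic Social-Network Simulation of Animal Group Fission
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of irreversible group fission driven by
    fission-fusion dynamics on a weighted, directed grooming-time network.
    Individuals leave a resting area each day for one of two resource areas
    with probabilities combining intrinsic (nutritional) motivation and a
    mimetic attraction toward groupmates already present; every temporary
    fission transfers a percentage of cross-subgroup grooming time onto
    within-subgroup links, and the group splits irreversibly once each
    individual allocates at least 95% of its social time within its own
    subgroup of four or more members. Provides a fast simulation engine with
    an independent plain-R replay, batch parameter sweeps over group size,
    Nutrition/Sociality ratio and transfer percentage, and the accompanying
    statistical analyses of days-to-fission (condition summaries, transfer
    linearity regression, Kruskal-Wallis with Dunn post-hoc grouping,
    Poisson regression, Kaplan-Meier survival curves), plus CSV/YAML/GraphML
    input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
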