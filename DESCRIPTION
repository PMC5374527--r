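Package: curp
Title: Agent-Based Simulation of Cooperation Under Resource Pressure
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A seedable agent-based model of resource sharing in small,
    well-mixed forager populations. Agents acquire a unit of energy
    stochastically each period, donate a heritable fraction of it to
    needy recipients chosen with a heritable partner-choice bias, and
    evolve by fitness-biased imitation with mutation. The package ships
    the full experimental apparatus used to study the model: Latin
    Hypercube parameter screening with random-forest variable
    importance (after PCA compression of the recorded state variables),
    a resource-pressure grid sweep, kernel-density maps of the
    strategy space, and regime summaries, together with a command-line
    interface, CSV trace output, and YAML configuration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    randomForest,
    MASS,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
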