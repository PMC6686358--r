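Package: spomlab
Title: Stochastic Patch Occupancy Models for Urban Tree-Base Plant Metapopulations
Version: 0.1.0
Authors@R:
    person("Bercy", "Flora Project", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and fit stochastic patch occupancy models (SPOMs)
    for plant metapopulations living at street tree bases. Implements four
    colonization-extinction models (Levins and propagule-rain, each with or
    without a rescue effect), forward Markov-chain simulation of annual
    occupancy surveys, maximum-likelihood estimation from occupancy time
    series with missing survey years, AICc model selection per street-species
    metapopulation, and quasi-binomial regressions relating best-model
    proportions to street geography and species traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
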