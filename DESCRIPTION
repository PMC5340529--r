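Package: seasipm
Title: Seasonal Eco-Evolutionary Integral Projection Model for Body-Size
    Driven Population Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-season integral projection model (IPM) in which
    body-size-dependent fecundity during the breeding season and
    size-and-density-dependent viability during the non-breeding season,
    together with direct and delayed density dependence, generate
    multigenerational cycles in population size and mean body size. Provides
    the deterministic one-generation engine (fecundity and survival kernels,
    environmental-effect means, season-to-season integral updates of
    abundance, mean breeding value and mean phenotype), a scenario simulator
    with crash detection (full model, stop-selection, no-viability-selection,
    no-delayed-density and low-heritability variants), cycle documentation via
    detrended autocorrelation functions, viability-selection statistics
    (standardized selection differentials, Welch tests, logistic survival
    fits, mixed-model selection-on-density and lagged density-dependence
    regressions), and an individual-based generator of experiment-shaped
    data (replicate fly populations, female dry weights, survival counts)
    for exercising every analysis without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
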