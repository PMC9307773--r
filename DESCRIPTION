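Package: biofiltr
Title: Dynamic Biofilter Simulation with Haldane Kinetics and Steady-State Multiplicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a gas-phase plug-flow biofilter column coupled through
    Henry's law to growing planar biofilms with substrate-inhibited (Haldane)
    degradation kinetics and a nitrogen-limited biomass cycle. Discretizes
    both the column and the biofilm by orthogonal collocation, integrates the
    coupled stiff system through arbitrary inlet-concentration schedules, and
    provides a steady-state boundary-value solver with natural-parameter
    continuation for detecting multiple coexisting biofilm states (high- vs
    low-activity branches) and the hysteresis window between them. Includes
    standard biofilter performance metrics (removal efficiency, loading rate,
    elimination capacity, empty-bed residence time), model-data comparison
    statistics, and generators for synthetic observation series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
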