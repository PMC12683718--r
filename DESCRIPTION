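Package: eldersim
Title: Agent-Based Simulation of Older Adults' Health-Facility Utilization and Equity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time agent-based simulation of how older adults use
    prevention, treatment, and long-term care facilities in a dense urban
    area, and of the health and equity consequences of that use. Agents with
    heterogeneous health, economic, and living status make daily outing and
    facility choices constrained by state-dependent activity radii; a
    continuous health value evolves under natural decay and per-visit facility
    gains. Includes a synthetic-city generator (clustered density surface,
    facility sites, agent homes, optional road-network distances), a weighted
    three-group Gini coefficient over subgroup mean health, four built-in
    policy intervention scenarios (comprehensive community hubs, senior-friendly
    transport, health education, and their combination) with a coverage-gap
    facility-siting algorithm, a paired-seed replicate experiment runner, and a
    univariate sensitivity protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
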