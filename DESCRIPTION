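Package: marginsim
Title: Agent-Based Simulation of Cultural Marginalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An aspatial agent-based model of discrete cultural trait
    transmission among four Merton-style subcultures (conformists, deviants,
    rebels and quiet mavericks). Agents exchange integer traits through
    trait-matched pairwise interactions whose success probabilities are set
    by a resistance-to-change (RTC) matrix; breed cultures are recompiled
    each tick as the eight most frequent pooled traits, agents switch breed
    when they hold a culture's full trait set, and agents are replaced after
    a fixed lifespan of interactions. The package runs the full
    RTC(3) x Diversity(3) factorial experiment, records population
    proportions, within-culture change and between-culture similarity, and
    analyses the replicate summaries with two-way ANOVA (classical
    eta-squared, Tukey HSD post-hocs). A compiled engine makes full-scale
    designs fast; a pure-R reference schedule backs the engine for
    verification at small scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
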