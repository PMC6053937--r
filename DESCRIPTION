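Package: alarmnet
Title: Heterospecific Alarm-Call Information Content and Communication Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing heterospecific alarm-call communication in
    multi-species animal communities. Computes information-content indices for
    alarm callers (caller consistency, call reliability, vulnerability weights
    from predator-preference indices, asymmetric body-size ratios), quantifies
    acoustic similarity between species' alarm calls, codes behavioural
    responses from playback-trial event logs, fits the associated suite of
    binomial, log-linear and negative-binomial mixed models with AICc-based
    all-subsets selection, and builds the directed interspecific communication
    network from response probabilities. A synthetic-community generator
    reproduces the statistical structure of predator-simulation and playback
    experiments so the entire pipeline can be exercised and validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    lme4,
    glmmTMB,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
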