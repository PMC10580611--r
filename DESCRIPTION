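Package: diversim
Title: Agent-Based Simulation of Buprenorphine Diversion and Opioid Overdose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-step agent-based simulator of prescription opioid use,
    opioid use disorder progression, treatment with medications for opioid
    use disorder, peer-network diversion of buprenorphine, and opioid
    overdose at statewide (North Carolina) scale.  Provides a scenario
    engine for comparing diversion policy counterfactuals (status quo,
    controlled prescription only, increased diversion), four sensitivity
    analyses, Monte-Carlo credible-interval summaries, and cumulative
    overdose curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
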