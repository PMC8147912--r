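Package: primsim
Title: Agent-Based Discrete-Event Simulation of Primary Care Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid agent-based / discrete-event simulator of primary care
    systems. Individually modeled patients develop acute and chronic illnesses
    and seek treatment with primary care physicians through appointments and
    walk-in visits; physicians schedule appointment slots, admit patients under
    a learning workload threshold, and treat them in priority order. The
    package generates synthetic scenarios from census-style population cells,
    runs replicated simulation experiments, accumulates patient- and
    physician-side key performance indicators with confidence intervals,
    detects warm-up truncation points with an initialization-bias test, and
    sweeps input parameters for sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    geosphere,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
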