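Package: mydriabim
Title: Budget Impact of Intracameral Versus Topical Mydriasis in Cataract Surgery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic budget impact model for a hospital cataract-surgery
    service comparing an intracameral mydriatic/anaesthetic injection with
    topical mydriatic eye drops. Computes annual resource use (nurse, surgeon
    and operating-room time, mydriasis failures), converts it into annual and
    per-patient costs, reports incremental costs and the throughput benefit of
    freed surgeon time, and runs a one-way deterministic sensitivity analysis
    with tornado ordering. A patient-level Monte Carlo microsimulation of the
    same decision tree serves as a stochastic oracle validating every cohort
    expectation. Scenarios are plain YAML or JSON files; a base-case scenario
    for a UK hospital performing 3,000 operations a year is packaged.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
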