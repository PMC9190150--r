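Package: nchdzone
Title: Delineation of Natural Catchment Health Districts from Patient Flow Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges health sub-districts into self-contained natural catchment
    health districts (NCHDs) from routine origin-destination birth-admission
    flows, using an adapted travel-to-work-area (TTWA) zone-design procedure:
    demand- and supply-side self-containment, a symmetric connectance index,
    an iterative hospital-anchored merge loop, and automated spatial
    contiguity repair. Includes a simpler scale-matched baseline delineation,
    per-zone access-to-care indicators (CEmONC readiness, midwife density,
    WHO staffing and facility benchmarks), a synthetic-scenario generator
    with gravity-model patient flows and planted-partition recovery mode,
    and readers and writers for the flow, facility, geography and population
    formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
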