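Package: twinconn
Title: Twin-Based Heritability Mapping of Task Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating genetic influences on brain phenotypes in
    classical twin designs. Implements ACE variance decomposition per phenotype
    element via Falconer's contrast and a non-iterative regression on squared
    twin-pair differences, permutation-based family-wise error control
    (max-statistic and cluster-extent), task-weighted ROI-to-ROI functional
    connectivity with condition contrasts, and a network-based-statistics test
    for a heritable connected component of the edgewise heritability matrix.
    Includes a synthetic twin-cohort generator (ACE-structured phenotypes, task
    event schedules, ROI time series with planted condition-dependent heritable
    connectivity, and motion traces) so the full pipeline is testable without
    access to restricted cohort data, plus quality-control exclusion rules
    (framewise displacement screening and robust amplitude-outlier removal with
    co-twin exclusion) and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
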