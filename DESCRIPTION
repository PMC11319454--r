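Package: sevcms
Title: Composite Measure Schemes for Postsurgical Severity Assessment in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite measure schemes (CMS) for evidence-based,
    comparative severity assessment of laboratory mice after surgical
    interventions. Starting from tidy per-animal welfare-monitoring
    observations (grimace scores, home-cage locomotion, voluntary wheel
    running, nest building, burrowing, body weight, fecal corticosterone
    metabolites, neurological scores), the package computes the derived
    severity parameters, removes redundant parameters by Spearman
    correlation screening, ranks the remaining parameters by resampled
    principal component analysis, and allocates animals to ordered
    severity classes by resampled k-means clustering on the principal
    component plane. A synthetic cohort generator emulating a
    three-group, multi-regimen, two-sex study design makes the whole
    pipeline runnable and testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
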