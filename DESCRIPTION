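Package: epmfaces
Title: Episodic Prototypes of Lifelong Face Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates how a lifelong stream of face exemplars condenses into
    episodic prototypes. Provides a synthetic generator for age-dependent
    face-feature trajectories with sudden appearance changes, a multiple-trace
    memory with threshold-delta prototype genesis and recency-weighted echo
    retrieval, a two-step clustering pipeline (Ward then k-means, with elbow
    and gap-statistic selection of the number of clusters), episodic /
    exhaustive / leave-one-out prototype construction, experiment-design
    enumeration with effect-size and reaction-time helpers, and scenario
    templates that wire the pieces into end-to-end in-silico studies.
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
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
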