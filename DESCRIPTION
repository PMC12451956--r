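Package: kynuscreen
Title: In-Silico Screening and Functional Profiling of Bacterial Kynureninases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for screening oral bacteria for functional
    kynureninase (KynU) candidates: presence/absence screening of kynurenine
    pathway genes (tdo, ido, kynU) from ortholog tables, BLAST tabular hits
    and an oral-taxon whitelist; global pairwise protein alignment and
    percent-identity matrices; rigid-body (Kabsch) superposition with RMSD;
    TM-score computation with length-dependent d0 scaling, a deterministic
    superposition-search heuristic and fold-similarity classification;
    expected molecular weights of His-tagged expression constructs; and
    calibration-curve quantification of kynurenine-pathway metabolites from
    LC-MS peak areas with detection-limit censoring and replicate
    summarisation. Includes seed-deterministic synthetic fixture generators
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
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
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
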