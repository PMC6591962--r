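Package: cfdecon
Title: Tissue-of-Origin Deconvolution of Plasma Cell-Free DNA from
    Methylation Marker Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping the tissue of origin of
    plasma cell-free DNA (cfDNA) from targeted methylation sequencing of
    CGCGCGG-anchored CpG-island loci. Converts per-molecule methylation
    calls into fully-methylated-molecule counts per million mapped reads
    (MePM), identifies loci differentially methylated between plasma and
    white blood cells, selects tissue-specific hypermethylation markers
    with a tau specificity index, and estimates per-tissue cfDNA fractions
    by solving the constrained linear mixture system with particle swarm
    optimization, including white-blood-cell background correction,
    conversion to absolute genomic equivalents per millilitre, and
    spike-in simulations for accuracy and detection-limit evaluation. A
    seeded synthetic-data generator reproduces the statistical structure
    of the assay so the whole pipeline is testable without sequencing
    data.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
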