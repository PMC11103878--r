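Package: chromadapt
Title: Drought-Induced Transcriptome and 3D Chromatin Reorganisation in Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of drought response in an allotetraploid genome
    across a two-variety, two-treatment, four-stage design: drought-induced gene
    calling and post-rewatering recovery classification, subgenome homoeolog
    expression-bias statistics (direction categories, stable/dynamic bias, the
    bias-change index and its genome-wide sum), A/B compartment calling from
    binned Hi-C contact matrices with four-stage switch-pattern classification,
    TAD boundary comparison (pan-boundary construction, drought gain/loss,
    fusion and Neo-TAD event detection, hotspot calling), and an integrative
    three-evidence target-gene screen on co-expression networks. Includes a
    synthetic-data generator that emulates the study design with ground-truth
    labels for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
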