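Package: msapkit
Title: Methylation-Sensitive Amplified Polymorphism (MSAP) Analysis and
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scoring and analysis of methylation-sensitive amplified
    polymorphism (MSAP) assays based on the HpaII/MspI isoschizomer pair.
    Classifies band presence/absence patterns into the four canonical MSAP
    band types, computes per-sample and pooled methylation summaries,
    classifies paired control/treatment banding patterns into the sixteen
    comparative classes with their no-change/demethylation/methylation
    grouping, and tests association between methylation classification and
    experimental condition with Pearson chi-square statistics backed by a
    margin-preserving permutation oracle. Also calls per-cytosine
    methylation from bisulfite-converted clone sequences in CG/CHG/CHH
    contexts, and forward-simulates both the MSAP assay (methylation
    states, isoschizomer digestion, band-scoring noise) and bisulfite
    conversion, so every analysis stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
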