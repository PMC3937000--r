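Package: genoprof
Title: Genome Profiling Simulation and Genomic Distance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and analysis of genome profiling (GP)
    experiments on plant cell lineages. Simulates somatic point-mutation
    accumulation along a tree's branch geometry, emulates the GP measurement
    (single-primer mismatch-tolerant random PCR followed by micro
    temperature-gradient gel electrophoresis rendered as mobility/melting
    feature points), performs internal-reference normalization to spiddos,
    computes pattern similarity scores (PaSS) and genomic distances (dG),
    clusters samples with Ward's method, and carries out the mutation-rate
    arithmetic linking genomic distance to cell-generation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
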