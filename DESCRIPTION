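Package: ogcpipe
Title: Orthologous Gene Cluster Construction, Phyletic Classification and
    GO Enrichment for Plant-Algal Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds orthologous gene clusters (OGCs) from filtered all-vs-all
    protein similarity hits with a from-scratch Markov cluster (MCL)
    implementation, classifies each OGC into one of nine phyletic groups
    across chlorophyte, charophyte (KCM/ZCC) and embryophyte clades,
    transfers Gene Ontology terms from best reference hits, and tests
    level-restricted GO terms for over-representation against a control
    group with an exact binomial test and multiple-testing adjustment.
    Includes a synthetic-cohort generator with known ground truth so the
    whole analysis is exercisable without real proteomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
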