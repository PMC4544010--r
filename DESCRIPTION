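Package: stemhet
Title: Subpopulation Structure and Switching Dynamics of Pluripotency Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dissecting heterogeneity in embryonic stem cell
    cultures: threshold-based classification of single-molecule RNA FISH
    transcript counts into nested marker-negative subpopulations,
    co-expression contingency and hypergeometric overlap statistics, a greedy
    gene-ontology category summarization that prevents related terms from
    crowding enrichment lists, post-processing of differential-expression
    tables (Benjamini-Hochberg hit calling, coherent/incoherent fold-change
    quadrants, transcription-factor binding overlap, directional gene-set
    summaries), and a two-state/mixture population model of marker-state
    switching with simulation and rate fitting for sort-regeneration
    experiments. Includes seeded synthetic-data generators emulating the
    single-cell and bulk measurement designs the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    deSolve,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
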