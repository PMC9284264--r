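Package: hybex
Title: Expression-Level Dominance and Transgressive Regulation in Hybrid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attributing hybrid vigor (heterosis) to gene expression
    patterns in F1 hybrids and their parents. Pairs homologous genes between
    two parental genomes by reciprocal best alignment hits, calls differential
    expression with a closed-form negative-binomial Wald test, classifies each
    homolog pair into one of twelve expression-pattern bins (additivity,
    expression-level dominance toward either parent, and transgressive up- or
    down-regulation), summarises pattern proportions and cross-stage
    intersections, computes mid-parent and over-parent heterosis indices with
    high-parent significance tests, and performs hypergeometric term
    enrichment. A seeded synthetic-data generator emulates the reciprocal
    interspecific cotton cross design (four materials, three seedling stages,
    two replicates) with planted pattern truth for end-to-end validation.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
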