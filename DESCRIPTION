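Package: cervcomp
Title: Cross-Species Comparative Transcriptomics of Cervical Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing stage-dependent gene expression
    across species from bulk RNA-seq counts: ortholog-restricted TPM
    normalization, square-root variance stabilization, sample-correlation
    quality control, within-species stage-contrast testing (one-way ANOVA,
    Student t, Kruskal-Wallis), cross-species direction-of-change concordance
    over a one-to-one ortholog map, gene-family paralog profiling against a
    pruned gene tree, and Fitch parsimony mapping of expression-modulation
    characters onto a species phylogeny. A seeded negative-binomial
    multi-species count simulator with planted effects makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
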