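Package: patmicro
Title: Microbiome and Host-Response Analysis Under Early-Life Antibiotic Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for studying the effect of a pulsed early-life
    antibiotic course (PAT) on the developing gut microbiome and host intestinal
    gene expression. Implements (i) presence calling of biosynthetic gene
    clusters (BGCs) from shotgun-metagenomic coverage using the Lander-Waterman
    expected-coverage probability, with Fisher-exact group enrichment and
    ORF-composition homology clustering; (ii) a five-class classification of
    longitudinal gene-expression maturation between two developmental
    timepoints in treated versus control arms, with pathway over-representation
    testing; and (iii) a compositionally aware sparse partial least squares
    (sPLS) association network between taxa and host genes, with StARS
    stability selection and bootstrap empirical p-values. A synthetic-data
    module generates all inputs with the statistical structure the analyses
    assume, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
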