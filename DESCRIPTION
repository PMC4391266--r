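Package: guildphylo
Title: Genome-Scale Phylogenetics and Trophic-Guild Gene-Content Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable phylogenomics pipeline for delineating bacterial
    higher taxa and trophic guilds from whole proteomes: all-vs-all protein
    similarity (exact Smith-Waterman with Karlin-Altschul E-values, or
    ingested BLAST tables), Markov clustering of homolog families
    (TribeMCL-style) and reciprocal-best-hit ortholog families with
    inparalog removal, progressive alignment with conserved-block
    filtering, construction of supermatrix, information-filtered,
    core-genes and binary gene-content character matrices, tree inference
    by neighbor joining, Fitch parsimony and maximum likelihood with
    bootstrap support and composite multi-method support annotation, and
    COG functional-category guild profiling. Includes a genome-evolution
    simulator with known species tree, gene family structure and planted
    guild signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
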