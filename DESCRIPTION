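Package: pelagomics
Title: Gene Catalogs, Strain Detection and Nitrogen-Pathway Analysis for
    Surface-Ocean Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of surface-ocean shotgun metagenomes:
    construction of nonredundant gene catalogs by greedy identity/coverage
    clustering and merging of independently derived gene sets; gene-length
    normalized relative-abundance profiling at gene, KEGG-Orthology and
    taxon level; pangenome read-recruitment strain detection and
    quantification; a declarative pathway engine for nitrogen-assimilation
    routes, nitrogen-cycle module presence and amino-acid biosynthesis gap
    analysis with transporter compensation; single-copy-gene phylogenetics
    (p-distance, neighbor-joining, ecotype clade assignment, average
    nucleotide identity); and the association statistics used in such
    surveys (permutation Spearman tests, Welch t-tests). A synthetic-data
    module simulates multi-strain communities with known abundances,
    pangenomes, near-duplicate gene variants and environmental covariates
    so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
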