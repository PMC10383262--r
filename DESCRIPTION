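Package: mgskit
Title: Signature-Gene Metagenomic Species Profiling and Cohort Contrasts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for shotgun-metagenomics abundance profiling with the
    metagenomic species (MGS) concept: classification of read-pair
    alignments against a gene catalog, signature-gene counting with
    effective-length normalization, tiered eight-rank taxonomic annotation
    of MGS from BLAST-style hit tables, Gut Metabolic Module (GMM)
    functional profiling including manually curated fucose and sialic-acid
    degradation modules, ecological analysis (downsampling, alpha
    diversity, weighted UniFrac, PCoA, PERMANOVA) and pairwise feeding-group
    contrasts (Mann-Whitney U, Cliff's delta, Benjamini-Hochberg FDR).
    Includes a synthetic-data generator that emulates a three-arm
    longitudinal infant cohort for validation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr,
    ape,
    vegan,
    Biostrings,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    jsonlite
biocViews: Metagenomics, Microbiome, Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
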