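Package: srpcensus
Title: Census of Prophages and CRISPR Arrays in Sulfate-Reducing Prokaryote Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for surveying prophages and CRISPR arrays across
    genomes of sulfate-reducing prokaryotes (SRP) and relating their carriage to
    host ecophysiology. Combines two independent prophage detectors' genomic
    intervals into consensus calls, filters CRISPR arrays by detection evidence
    level, estimates cell volume and surface area from cell dimensions, computes
    per-strain and per-cell prophage burden, builds a prophage-prophage protein
    homology network with thresholded edges, reconstructs a neighbor-joining
    bootstrap phylogeny from a curated protein alignment, and runs the
    association statistics (Spearman, Wilcoxon, Fisher/odds ratio, PCA) linking
    carriage to traits. Includes a synthetic-data generator that emulates every
    input so all stages are testable without external detector software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    igraph,
    IRanges,
    methods,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
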