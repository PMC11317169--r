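Package: aptafootseq
Title: SELEX Enrichment Analysis and Aptamer Footprinting by Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of SELEX (Systematic Evolution of Ligands by
    Exponential enrichment) next-generation sequencing data and of
    aptamer-mixture binding assays read out by sequencing. Recovers
    random regions from amplicon reads by anchored primer trimming,
    builds per-round frequency tables, clusters abundant candidate
    sequences into families by Levenshtein edit distance, scores
    conserved motifs by approximate substring search, computes
    normalized enrichment ratios (RN) and median binding footprints for
    a defined aptamer panel, and compares footprints by
    Pearson-correlation distance with hierarchical clustering and
    Newick export. Includes a synthetic-data generator (SELEX round
    series and assay count tables with planted ground truth) so every
    stage can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    yaml
Config/testthat/edition: 3
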