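Package: springcomm
Title: Marker-Gene and Genome-Resolved Profiling of Geothermal Spring
    Archaeal Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for community analysis of geothermal spring
    metagenomes built around the single-copy ribosomal protein S3 (rpS3) marker
    gene. Identifies confirmed rpS3 genes from candidate search results, collapses
    them to species-level representatives by greedy 99% identity clustering,
    assigns GTDB-style taxonomy with a bootstrap-confidence naive Bayes classifier
    and a top-hit lowest-concordant-rank fallback, curates genome bins by
    interquartile-range depth filtering, estimates completeness and contamination
    from single-copy marker inventories (including a reduced 48-gene set for DPANN
    Archaea), dereplicates genomes at 99% average nucleotide identity, computes
    coverage-weighted relative abundances and genome-to-marker linkage metrics,
    runs community ecology statistics (Bray-Curtis, PCoA, ANOSIM, Pearson),
    profiles pathway presence and metabolic weight scores, and infers SparCC
    co-occurrence networks with bootstrap pseudo p-values. A synthetic-data module
    generates multi-sample spring communities with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
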