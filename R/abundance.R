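# Relative abundance bookkeeping for rMAGs and rpS3 marker genes, the 0.01%
# reporting floor, genome-to-marker linkage metrics, rank aggregation, and
# FPKM for transcript counts. Abundance matrices are plain numeric matrices
# with features as rows and samples as columns; values are fractions unless
# stated otherwise.

#' Relative abundance of representative genomes from read mapping
#'
#' Abundance of an rMAG in a sample is the fraction of that sample's mapped
#' reads recruited by the rMAG. Entries at or below the reporting floor
#' (default 0.01%, i.e. only abundances strictly greater than the floor are
#' counted) are set to zero; no re-normalization is applied afterwards, so
#' per-sample sums may fall below 1.
#'
#' @param mapped_reads Numeric matrix rMAG x sample of mapped read counts.
#' @param total_reads Named numeric vector of total mapped reads per sample.
#' @param floor Reporting floor as a fraction (default 1e-4 = 0.01%).
#' @return Matrix rMAG x sample of abundance fractions.
#' @export
rmag_abundance <- function(mapped_reads, total_reads, floor = 1e-4) {
  mapped_reads <- as.matrix(mapped_reads)
  if (is.null(names(total_reads))) names(total_reads) <- colnames(mapped_reads)
  total_reads <- total_reads[colnames(mapped_reads)]
  if (any(!is.finite(total_reads)) || any(total_reads <= 0)) {
    abort("total_reads must be positive for every sample")
  }
  if (any(colSums(mapped_reads) > total_reads + 1e-9)) {
    abort("mapped reads exceed total reads in some sample")
  }
  ab <- sweep(mapped_reads, 2, total_reads, `/`)
  ab[ab <= floor] <- 0
  ab
}

#' Coverage and relative abundance of marker genes
#'
#' Coverage of a marker is its recruited read count divided by the gene
#' length; relative abundance is that coverage divided by the summed marker
#' coverage of the sample.
#'
#' @param read_counts Numeric matrix marker x sample.
#' @param gene_lengths Named numeric vector of gene lengths in bp.
#' @return List with `coverage` and `abundance` matrices (marker x sample).
#'   Samples with zero total coverage get `NA` abundances with a warning.
#' @export
marker_abundance <- function(read_counts, gene_lengths) {
  read_counts <- as.matrix(read_counts)
  gene_lengths <- gene_lengths[rownames(read_counts)]
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    abort("gene lengths must be positive for every marker")
  }
  coverage <- sweep(read_counts, 1, gene_lengths, `/`)
  totals <- colSums(coverage)
  if (any(totals == 0)) {
    warning("sample(s) with zero marker coverage reported as NA: ",
            paste(colnames(coverage)[totals == 0], collapse = ", "))
  }
  abundance <- sweep(coverage, 2, totals, `/`)
  abundance[, totals == 0] <- NA_real_
  list(coverage = coverage, abundance = abundance)
}

#' Genome-to-marker linkage metrics
#'
#' Quantifies how well a set of genomes captures the marker-gene view of the
#' community. A representative marker is "contained" in a genome when any
#' member of its cluster is among the genome's genes.
#'
#' @param mag_genes Named list: bin id -> character vector of gene ids
#'   contained in that genome.
#' @param clusters Data frame `centroid_id`, `member_id` (from
#'   [cluster_representatives()]).
#' @param coverages Named numeric vector of representative (centroid)
#'   coverages.
#' @return List with `pct_mags_with_marker`, `pct_markers_in_mags_by_count`,
#'   `pct_markers_in_mags_by_coverage` (all percentages).
#' @export
linkage_metrics <- function(mag_genes, clusters, coverages) {
  reps <- unique(clusters$centroid_id)
  if (length(reps) == 0L) abort("representative set is empty")
  all_mag_genes <- unique(unlist(mag_genes, use.names = FALSE))
  contained <- vapply(reps, function(cid) {
    members <- clusters$member_id[clusters$centroid_id == cid]
    any(members %in% all_mag_genes)
  }, logical(1))
  has_marker <- vapply(mag_genes, function(g) {
    any(g %in% clusters$member_id)
  }, logical(1))
  cov <- coverages[reps]
  cov[is.na(cov)] <- 0
  list(
    pct_mags_with_marker = 100 * mean(has_marker),
    pct_markers_in_mags_by_count = 100 * mean(contained),
    pct_markers_in_mags_by_coverage =
      if (sum(cov) > 0) 100 * sum(cov[contained]) / sum(cov) else NA_real_
  )
}

#' Aggregate an abundance matrix at a taxonomic rank
#'
#' Sums member abundances per rank label; features without an assignment at
#' that rank (partial lineages) pool into `"Unclassified"`. Per-sample column
#' sums are preserved.
#'
#' @param matrix Feature x sample abundance matrix.
#' @param lineages Named list of `taxonomic_lineage`s (or character vectors of
#'   rank labels named by rank), one per feature.
#' @param rank One of domain, phylum, class, order, family, genus, species.
#' @return Aggregated matrix, rank labels as rows.
#' @export
aggregate_by_rank <- function(matrix, lineages, rank) {
  if (!rank %in% RANKS) {
    abort("unknown rank '", rank, "'; use one of ", paste(RANKS, collapse = ", "))
  }
  matrix <- as.matrix(matrix)
  labels <- vapply(rownames(matrix), function(f) {
    lin <- lineages[[f]]
    labs <- unclass(lin)
    i <- match(rank, RANKS)
    if (!is.null(labs) && length(labs) >= i) labs[[i]] else "Unclassified"
  }, character(1))
  rowsum(matrix, group = labels)
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count / (length_kb * library_size / 1e6)`.
#'
#' @param fragment_counts Numeric vector of mapped fragment counts.
#' @param gene_lengths Gene lengths in bp (> 0).
#' @param library_size Total mapped fragments in the library (> 0).
#' @return Numeric vector of FPKM values.
#' @examples
#' fpkm(10, 2000, 1e6)  # 5
#' @export
fpkm <- function(fragment_counts, gene_lengths, library_size) {
  if (length(library_size) != 1L || !is.finite(library_size) || library_size <= 0) {
    abort("library_size must be a single positive number")
  }
  if (any(gene_lengths <= 0)) abort("gene lengths must be positive")
  fragment_counts / ((gene_lengths / 1000) * (library_size / 1e6))
}
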