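# End-to-end orchestration: candidate screening -> reference confirmation ->
# 99% clustering -> taxonomy assignment of representatives -> coverage-based
# marker abundance -> rank aggregation -> group statistics.

#' Profile a spring community end to end
#'
#' Runs the full marker pipeline on a (synthetic or real) spring dataset:
#' screens candidates by score and translated length, confirms them against
#' the labelled reference set, clusters confirmed genes at the species-level
#' identity threshold, assigns each representative a taxonomy
#' (bootstrap-confidence classifier with LCA fallback), builds the
#' representative x sample abundance matrix from read counts, aggregates it
#' at the requested rank, and tests the compositional difference between pH
#' classes with ANOSIM on Bray-Curtis distances.
#'
#' @param dataset A `spring_dataset` (or a list with compatible
#'   `candidates`, `read_counts`, `refs`, `metadata`, `gene_length`).
#' @param score_min,len_min_aa Screening thresholds (defaults 40 / 60).
#' @param confirm_identity Best-hit identity to confirm a marker (default
#'   0.60).
#' @param cluster_identity Representative clustering identity (default 0.99).
#' @param rank Aggregation rank for the community table (default "order").
#' @param permutations ANOSIM permutations (default 999).
#' @param seed Integer seed for classification bootstraps and permutations.
#' @return List with `confirmed`, `clusters`, `assignments` (named list of
#'   `taxonomic_lineage`s per representative), `abundance` (representative x
#'   sample), `community` (rank-aggregated), `anosim` (`R`, `p`), `groups`.
#' @export
profile_community <- function(dataset, score_min = 40, len_min_aa = 60,
                              confirm_identity = 0.60, cluster_identity = 0.99,
                              rank = "order", permutations = 999, seed = 1) {
  screened <- screen_candidates(dataset$candidates, score_min, len_min_aa)
  confirmed <- confirm_markers(screened, dataset$refs, confirm_identity)
  cl <- cluster_representatives(confirmed, identity = cluster_identity)

  db <- as_ref_db(dataset$refs)
  reps <- cl$centroids
  assignments <- lapply(seq_len(nrow(reps)), function(i) {
    assign_taxonomy(reps$sequence[i], db, seed = child_seed(seed, i))
  })
  names(assignments) <- reps$gene_id

  # representative x sample read counts: member genes pooled per cluster
  rc <- dataset$read_counts
  member_of <- stats::setNames(cl$clusters$centroid_id, cl$clusters$member_id)
  rc <- rc[rc$gene_id %in% names(member_of), , drop = FALSE]
  rc$rep_id <- unname(member_of[rc$gene_id])
  samples <- dataset$metadata$sample_id
  counts <- matrix(0, nrow = nrow(reps), ncol = length(samples),
                   dimnames = list(reps$gene_id, samples))
  agg <- stats::aggregate(read_count ~ rep_id + sample_id, data = rc, FUN = sum)
  counts[cbind(agg$rep_id, agg$sample_id)] <- agg$read_count

  lens <- stats::setNames(rep(dataset$gene_length, nrow(reps)), reps$gene_id)
  ab <- marker_abundance(counts, lens)
  community <- aggregate_by_rank(ab$abundance, assignments, rank)

  groups <- assign_groups(dataset$metadata)
  usable <- !groups$ungrouped & colSums(community, na.rm = TRUE) > 0
  d <- bray_curtis(community[, usable, drop = FALSE])
  an <- anosim(d, groups$ph_class[usable], permutations = permutations,
               seed = child_seed(seed, 9999))
  list(screened = screened, confirmed = confirmed, clusters = cl,
       assignments = assignments, abundance = ab$abundance,
       coverage = ab$coverage, community = community,
       groups = groups, anosim = an)
}
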