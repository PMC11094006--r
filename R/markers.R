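# rpS3 marker identification: candidate screening, reference confirmation,
# global-alignment identity, and greedy centroid clustering at 99% identity.

#' Build a marker record table
#'
#' Marker records carry one candidate or confirmed rpS3 gene per row:
#' `gene_id`, `sample_id`, `sequence` (uppercase ACGT), `length_aa` (translated
#' length in amino acids; defaults to `floor(nchar(sequence)/3)`), `score` (the
#' upstream search score, provided as input) and `coverage` (reads per bp).
#'
#' @param gene_id,sample_id Character vectors.
#' @param sequence Character vector of nucleotide sequences.
#' @param score Numeric search scores (>= 0).
#' @param length_aa Optional translated lengths; derived from the sequence
#'   when missing.
#' @param coverage Optional read coverages (reads per bp), default 0.
#' @return A data frame of class `marker_records`.
#' @export
marker_records <- function(gene_id, sample_id, sequence, score,
                           length_aa = NULL, coverage = 0) {
  if (is.null(length_aa)) length_aa <- floor(nchar(sequence) / 3)
  df <- data.frame(gene_id = as.character(gene_id),
                   sample_id = as.character(sample_id),
                   sequence = as.character(sequence),
                   length_aa = as.numeric(length_aa),
                   score = as.numeric(score),
                   coverage = as.numeric(coverage),
                   stringsAsFactors = FALSE)
  if (any(df$score < 0) || any(df$length_aa < 0)) {
    abort("scores and lengths must be non-negative")
  }
  if (any(df$sequence == "")) abort("sequences must be non-empty")
  if (anyDuplicated(df[, c("gene_id", "sample_id")])) {
    abort("gene_id must be unique within a sample")
  }
  class(df) <- c("marker_records", "data.frame")
  df
}

#' Screen marker candidates by search score and translated length
#'
#' Reproduces the two quantitative steps of the three-step rpS3 screen: hits
#' with search score below `score_min` are filtered out, and sequences whose
#' translated length falls below `len_min_aa` amino acids are eliminated.
#' Both removals are strict (`score < 40` drops, `score = 40` is kept).
#'
#' @param candidates A `marker_records` data frame.
#' @param score_min Minimum search score (default 40).
#' @param len_min_aa Minimum translated length in amino acids (default 60).
#' @return The kept records, input order preserved.
#' @examples
#' recs <- marker_records(c("g1", "g2"), "s1", c("ATGAAA", "ATGCCC"),
#'                        score = c(39.9, 40), length_aa = c(100, 60))
#' screen_candidates(recs)$gene_id
#' @export
screen_candidates <- function(candidates, score_min = 40, len_min_aa = 60) {
  if (score_min <= 0 || len_min_aa <= 0) abort("thresholds must be positive")
  if (nrow(candidates) == 0L) return(candidates)
  keep <- candidates$score >= score_min & candidates$length_aa >= len_min_aa
  candidates[keep, , drop = FALSE]
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2, linear
#' gap cost); identity is the number of matching columns divided by the total
#' number of alignment columns, so gap columns count as mismatches.
#' Symmetric, in \[0, 1\], and 1 for identical sequences. Ties between
#' equal-scoring alignments are broken deterministically (diagonal moves
#' preferred in the traceback).
#'
#' @param a,b Non-empty ACGT strings.
#' @return Identity fraction.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  check_sequence(a, "a")
  check_sequence(b, "b")
  nw_identity_cpp(a, b)
}

# identity of one query against many references (named vector)
identity_to_refs <- function(query, ref_seqs) {
  stats::setNames(nw_identity_batch(query, unname(ref_seqs)), names(ref_seqs))
}

#' Confirm screened candidates against a labelled reference set
#'
#' A screened record is confirmed as rpS3 iff its best global-alignment
#' identity to any reference marker reaches `min_identity`. This replaces an
#' external-database protein search with a best-hit test against the supplied
#' labelled reference set, preserving the keep/drop contract.
#'
#' @param screened A `marker_records` data frame.
#' @param reference_markers A `marker_refs` object or named character vector
#'   of reference sequences.
#' @param min_identity Minimum best-hit identity (default 0.60 in nucleotide
#'   space).
#' @return Confirmed records with a `best_identity` column appended.
#' @export
confirm_markers <- function(screened, reference_markers, min_identity = 0.60) {
  ref_seqs <- if (inherits(reference_markers, "marker_refs")) {
    reference_markers$sequences
  } else {
    reference_markers
  }
  if (length(ref_seqs) == 0L) {
    abort("reference set is empty", class = "springcomm_config_error")
  }
  check_fraction(min_identity, "min_identity")
  if (nrow(screened) == 0L) {
    out <- screened
    out$best_identity <- numeric(0)
    return(out)
  }
  best <- vapply(screened$sequence,
                 function(q) max(identity_to_refs(q, ref_seqs)), numeric(1))
  out <- screened[best >= min_identity, , drop = FALSE]
  out$best_identity <- unname(best[best >= min_identity])
  out
}

#' Greedy centroid clustering of confirmed markers
#'
#' Mirrors length-sorted greedy centroid clustering with exhaustive centroid
#' comparison (the USEARCH `-sort length -maxaccepts 0 -maxrejects 0
#' -centroids` recipe): records are processed by decreasing sequence length
#' (ties broken by lexicographic `gene_id` for reproducibility); each record
#' joins the best existing centroid with identity >= the threshold, otherwise
#' it founds a new cluster.
#'
#' @param confirmed A `marker_records` data frame.
#' @param identity Identity threshold in (0, 1], default 0.99.
#' @return A list of class `marker_clusters`: `clusters` (data frame
#'   `centroid_id`, `member_id`) and `centroids` (the centroid records).
#' @export
cluster_representatives <- function(confirmed, identity = 0.99) {
  check_fraction(identity, "identity", lo_open = TRUE)
  if (nrow(confirmed) == 0L) {
    return(structure(list(
      clusters = data.frame(centroid_id = character(0), member_id = character(0),
                            stringsAsFactors = FALSE),
      centroids = confirmed, identity = identity), class = "marker_clusters"))
  }
  key <- if (anyDuplicated(confirmed$gene_id)) {
    paste(confirmed$sample_id, confirmed$gene_id, sep = ":")
  } else {
    confirmed$gene_id
  }
  ord <- order(-nchar(confirmed$sequence), key)
  recs <- confirmed[ord, , drop = FALSE]
  keys <- key[ord]
  cent_idx <- integer(0)        # row indices of centroids within recs
  assign_to <- integer(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    placed <- FALSE
    if (length(cent_idx) > 0L) {
      ids <- nw_identity_batch(recs$sequence[i], recs$sequence[cent_idx])
      # exhaustive comparison: best centroid meeting the threshold wins
      ok <- which(ids >= identity)
      if (length(ok) > 0L) {
        assign_to[i] <- cent_idx[ok[which.max(ids[ok])]]
        placed <- TRUE
      }
    }
    if (!placed) {
      cent_idx <- c(cent_idx, i)
      assign_to[i] <- i
    }
  }
  clusters <- data.frame(centroid_id = keys[assign_to], member_id = keys,
                         stringsAsFactors = FALSE)
  structure(list(clusters = clusters,
                 centroids = recs[cent_idx, , drop = FALSE],
                 identity = identity),
            class = "marker_clusters")
}

#' @export
print.marker_clusters <- function(x, ...) {
  cat("marker_clusters:", nrow(x$centroids), "clusters over",
      nrow(x$clusters), "records at identity", x$identity, "\n")
  invisible(x)
}
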