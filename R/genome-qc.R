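# Genome-bin curation, quality estimation, and strain-level dereplication.
#
# Bins are curated by an interquartile-range rule on scaffold read depth;
# completeness/contamination come from single-copy marker inventories (a
# reduced 48-gene set for DPANN Archaea, a 53-gene set otherwise); bins
# passing completeness > 50% and contamination < 10% are dereplicated at 99%
# ANI with a dRep-style greedy scheme (score = completeness - 5 x
# contamination).

#' Single-copy marker inventories used for completeness estimation
#'
#' Returns the two marker-gene inventories the quality estimator expects:
#' `standard` (53 archaeal single-copy genes) and `dpann48` (the reduced
#' 48-gene set appropriate for small-genome DPANN Archaea). The identifiers
#' are synthetic placeholders paired with the synthetic-data generator; any
#' user-supplied inventory of real marker ids can be passed instead.
#'
#' @return List with character vectors `standard` and `dpann48`.
#' @export
archaeal_marker_sets <- function() {
  list(standard = sprintf("SCG%03d", 1:53),
       dpann48 = sprintf("DPANN%02d", 1:48))
}

#' Construct a genome bin
#'
#' @param bin_id,sample_id Identifiers.
#' @param scaffolds Data frame with columns `scaffold_id`, `length_bp`,
#'   `depth` and optionally `sequence`.
#' @param markers Named integer vector: single-copy marker id -> copy count.
#' @param is_dpann Logical: use the reduced 48-gene marker set?
#' @param annotations Optional data frame (`gene_id`, `ko`, `cazy_family`,
#'   `scaffold_id`).
#' @param gene_ids Optional character vector of marker gene ids contained in
#'   the bin (used for genome-to-marker linkage).
#' @return An object of class `genome_bin`.
#' @export
genome_bin <- function(bin_id, sample_id, scaffolds, markers = integer(0),
                       is_dpann = FALSE, annotations = NULL,
                       gene_ids = character(0)) {
  if (!all(c("scaffold_id", "length_bp", "depth") %in% names(scaffolds))) {
    abort("scaffolds need columns scaffold_id, length_bp, depth")
  }
  if (anyDuplicated(scaffolds$scaffold_id)) abort("scaffold ids must be unique")
  if (any(scaffolds$depth < 0)) abort("depths must be >= 0")
  if (length(markers) > 0 && any(markers < 0)) abort("copy counts must be >= 0")
  structure(list(bin_id = bin_id, sample_id = sample_id,
                 scaffolds = scaffolds, markers = markers,
                 is_dpann = isTRUE(is_dpann), annotations = annotations,
                 gene_ids = gene_ids),
            class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat("genome_bin", x$bin_id, "-", nrow(x$scaffolds), "scaffolds,",
      sum(x$markers > 0), "distinct markers",
      if (x$is_dpann) "(DPANN)" else "", "\n")
  invisible(x)
}

#' Remove scaffolds with outlier read depth
#'
#' Computes Q1 and Q3 of the bin's scaffold depths with linear-interpolation
#' quantiles (R type 7) and removes scaffolds whose depth falls strictly
#' below `Q1 - 1.5 * IQR` or strictly above `Q3 + 1.5 * IQR`. When IQR = 0
#' the fences collapse onto the quartile value and nothing strictly outside
#' exists unless depths differ from it.
#'
#' @param bin A `genome_bin` with at least one scaffold.
#' @return List with `bin` (curated) and `removed` (data frame of removed
#'   scaffold ids and depths, plus the fences used).
#' @examples
#' b <- genome_bin("b1", "s1", data.frame(scaffold_id = paste0("c", 1:5),
#'        length_bp = 1000, depth = c(10, 11, 12, 13, 100)))
#' filter_depth_outliers(b)$removed$scaffold_id
#' @export
filter_depth_outliers <- function(bin) {
  if (!inherits(bin, "genome_bin")) abort("'bin' must be a genome_bin")
  if (nrow(bin$scaffolds) == 0L) abort("bin has no scaffolds")
  d <- bin$scaffolds$depth
  q <- stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  out <- d < lo | d > hi
  removed <- bin$scaffolds[out, c("scaffold_id", "depth"), drop = FALSE]
  attr(removed, "fences") <- c(lower = lo, upper = hi, q1 = q[1], q3 = q[2])
  bin$scaffolds <- bin$scaffolds[!out, , drop = FALSE]
  if (!is.null(bin$annotations) && nrow(removed) > 0L &&
      "scaffold_id" %in% names(bin$annotations)) {
    bin$annotations <-
      bin$annotations[!bin$annotations$scaffold_id %in% removed$scaffold_id, ,
                      drop = FALSE]
  }
  list(bin = bin, removed = removed)
}

#' Estimate bin completeness and contamination from single-copy markers
#'
#' Completeness is the percentage of expected single-copy markers present at
#' least once; contamination is `100 * (total copies - distinct markers
#' present) / (markers expected)`. DPANN bins are scored against the reduced
#' 48-gene set, others against the standard set. Tiers follow the MIMAG
#' convention: `high` for completeness > 90 and contamination < 5, `medium`
#' for completeness > 50 and contamination < 10, otherwise `fail`.
#'
#' @param bin A `genome_bin`.
#' @param marker_sets List with `standard` and `dpann48` inventories
#'   (default [archaeal_marker_sets()]).
#' @return An object of class `quality_report`.
#' @export
estimate_quality <- function(bin, marker_sets = archaeal_marker_sets()) {
  if (length(marker_sets$standard) == 0L || length(marker_sets$dpann48) == 0L) {
    abort("marker sets must be non-empty")
  }
  expected <- if (bin$is_dpann) marker_sets$dpann48 else marker_sets$standard
  inv <- bin$markers
  if (length(inv) > 0L) {
    known <- names(inv) %in% unlist(marker_sets, use.names = FALSE)
    if (!all(known)) {
      abort("unknown marker ids: ",
            paste(utils::head(names(inv)[!known], 3), collapse = ", "))
    }
    inv <- inv[names(inv) %in% expected]
  }
  present <- sum(inv > 0)
  completeness <- 100 * present / length(expected)
  contamination <- 100 * (sum(inv) - present) / length(expected)
  tier <- if (completeness > 90 && contamination < 5) "high"
          else if (completeness > 50 && contamination < 10) "medium"
          else "fail"
  structure(list(bin_id = bin$bin_id,
                 completeness = completeness, contamination = contamination,
                 marker_set = if (bin$is_dpann) "dpann48" else "standard",
                 scaffold_count = nrow(bin$scaffolds),
                 passes_gate = completeness > 50 && contamination < 10,
                 tier = tier),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report %s: %.1f%% complete, %.1f%% contaminated (%s, %s)\n",
              x$bin_id, x$completeness, x$contamination, x$marker_set, x$tier))
  invisible(x)
}

#' Medium-quality gate on a quality report
#'
#' Keep iff completeness > 50 and contamination < 10 (both strict, as the
#' inequalities are quoted).
#'
#' @param report A `quality_report`.
#' @return Logical.
#' @export
quality_gate <- function(report) {
  if (!inherits(report, "quality_report")) abort("'report' must be a quality_report")
  report$completeness > 50 && report$contamination < 10
}

bin_kmers <- function(bin, k = 21L) {
  seqs <- bin$scaffolds$sequence
  if (is.null(seqs) || all(is.na(seqs)) || sum(nchar(seqs)) == 0L) {
    abort("bin ", bin$bin_id, " has no sequence content")
  }
  seqs <- seqs[!is.na(seqs) & nchar(seqs) >= k]
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE))
}

#' Alignment-free ANI estimate from k-mer containment
#'
#' Estimates average nucleotide identity between two bins from 21-mer
#' containment `c = |A intersect B| / min(|A|, |B|)` mapped through the Mash
#' distance transform `ANI = 1 + log(2c / (1 + c)) / k`. Symmetric by
#' construction; identical bins give 1; unrelated sequences share essentially
#' no 21-mers and return 0.
#'
#' @param a,b `genome_bin`s with scaffold sequences.
#' @param k k-mer size (default 21).
#' @return ANI fraction in \[0, 1\].
#' @export
estimate_ani <- function(a, b, k = 21L) {
  ka <- bin_kmers(a, k)
  kb <- bin_kmers(b, k)
  cont <- length(intersect(ka, kb)) / min(length(ka), length(kb))
  if (cont == 0) return(0)
  max(0, 1 + log(2 * cont / (1 + cont)) / k)
}

#' Dereplicate quality-passing bins into representative genomes
#'
#' Greedy dereplication in the dRep spirit: bins are sorted by score
#' `completeness - 5 * contamination` (descending, ties broken by bin id);
#' each bin joins the first representative with ANI >= `ani_threshold`,
#' otherwise it founds a new representative (rMAG).
#'
#' @param bins List of `genome_bin`s (all expected to pass the quality gate).
#' @param reports List of matching `quality_report`s.
#' @param ani_threshold ANI threshold (default 0.99, strain level).
#' @return List of class `derep_result`: `representatives` (bin ids),
#'   `clusters` (data frame `rmag_id`, `member_bin_id`, `ani`), `scores`.
#' @export
dereplicate <- function(bins, reports, ani_threshold = 0.99) {
  check_fraction(ani_threshold, "ani_threshold", lo_open = TRUE)
  if (length(bins) == 0L) {
    return(structure(list(representatives = character(0),
                          clusters = data.frame(rmag_id = character(0),
                                                member_bin_id = character(0),
                                                ani = numeric(0)),
                          scores = numeric(0)), class = "derep_result"))
  }
  ids <- unname(vapply(bins, `[[`, "", "bin_id"))
  rep_ids <- unname(vapply(reports, `[[`, "", "bin_id"))
  reports <- reports[match(ids, rep_ids)]
  scores <- vapply(reports, function(r) r$completeness - 5 * r$contamination,
                   numeric(1))
  names(scores) <- ids
  ord <- order(-scores, ids)
  reps <- integer(0)
  out <- vector("list", length(bins))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      ani <- estimate_ani(bins[[r]], bins[[i]])
      if (ani >= ani_threshold) {
        out[[i]] <- data.frame(rmag_id = ids[r], member_bin_id = ids[i],
                               ani = ani, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      out[[i]] <- data.frame(rmag_id = ids[i], member_bin_id = ids[i],
                             ani = 1, stringsAsFactors = FALSE)
    }
  }
  structure(list(representatives = ids[reps],
                 clusters = do.call(rbind, out),
                 scores = scores),
            class = "derep_result")
}

#' @export
print.derep_result <- function(x, ...) {
  cat("derep_result:", length(x$representatives), "representatives from",
      nrow(x$clusters), "bins\n")
  invisible(x)
}
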