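# Self-consistent reference database curation and taxonomy assignment:
# a word-based naive Bayes classifier with bootstrap confidence (the classic
# RDP recipe: word size 8, 100 replicates, ceiling(W/8) words per replicate)
# plus a top-5 lowest-concordant-rank fallback for queries that cannot be
# assigned at phylum level.

WORD_SIZE <- 8L

sequence_words <- function(seq) {
  n <- nchar(seq)
  if (n < WORD_SIZE) abort("query shorter than word size (", WORD_SIZE, " nt)")
  unique(substring(seq, 1:(n - WORD_SIZE + 1L), WORD_SIZE:n))
}

# word-presence index over a set of reference sequences
build_word_index <- function(sequences) {
  word_list <- lapply(sequences, sequence_words)
  dict <- unique(unlist(word_list, use.names = FALSE))
  presence <- matrix(FALSE, nrow = length(sequences), ncol = length(dict))
  for (i in seq_along(word_list)) {
    presence[i, match(word_list[[i]], dict)] <- TRUE
  }
  n_refs <- length(sequences)
  prior <- (colSums(presence) + 0.5) / (n_refs + 1)    # word prior P_i
  # log conditional per reference: (presence + prior) / (M + 1), M = 1 copy
  list(dict = dict, logp = log(sweep(presence, 2, prior, `+`) / 2),
       prior_unseen = 0.5 / (n_refs + 1))
}

#' Build a taxonomic lineage object
#' @noRd
new_lineage <- function(labels, confidence = NULL, path = NA_character_) {
  structure(labels, confidence = confidence, path = path,
            class = "taxonomic_lineage")
}

#' @export
print.taxonomic_lineage <- function(x, ...) {
  cat(lineage_string(x), "\n")
  conf <- attr(x, "confidence")
  if (!is.null(conf)) {
    cat("confidence:", paste(sprintf("%s=%.2f", names(conf), conf),
                             collapse = " "), "\n")
  }
  if (!is.na(attr(x, "path"))) cat("path:", attr(x, "path"), "\n")
  invisible(x)
}

#' Semicolon-joined lineage string
#' @param lineage A `taxonomic_lineage`.
#' @return Single string, e.g. `"d__Archaea;p__Phylum_001"`.
#' @export
lineage_string <- function(lineage) {
  paste(unclass(lineage), collapse = ";")
}

#' Curate a labelled marker set into a species-level reference database
#'
#' Applies, in order: a strict length filter (`> min_len_bp`), exact-duplicate
#' collapse, a self-consistency filter (each sequence is classified with
#' itself withheld from training; it is discarded if any rank assigned with
#' confidence >= `confidence` disagrees with its recorded lineage), and
#' greedy clustering at `species_identity` to species-level representatives.
#'
#' @param raw A `marker_refs` object (sequences + lineages).
#' @param min_len_bp Length floor in bp; sequences of exactly this length are
#'   removed (default 300).
#' @param species_identity Identity for the final species-level clustering
#'   (default 0.99).
#' @param confidence Bootstrap confidence used by the self-consistency test
#'   (default 0.60).
#' @param bootstraps Bootstrap replicates for the self-consistency test.
#' @param seed Integer seed.
#' @return An object of class `curated_ref_db` with `sequences`, `lineages`,
#'   and a `curation_log` of per-stage removal counts.
#' @export
curate_reference_db <- function(raw, min_len_bp = 300, species_identity = 0.99,
                                confidence = 0.60, bootstraps = 100, seed = 1) {
  seqs <- raw$sequences
  lin <- raw$lineages
  if (length(seqs) == 0L) abort("raw reference set is empty")
  if (is.null(names(seqs))) names(seqs) <- lin$species_id
  log <- c(input = length(seqs), length_filter = 0L, duplicate_collapse = 0L,
           self_consistency = 0L, species_clustering = 0L)

  keep <- nchar(seqs) > min_len_bp
  log[["length_filter"]] <- sum(!keep)
  seqs <- seqs[keep]; lin <- lin[keep, , drop = FALSE]
  empty_db_check(seqs, log)

  dup <- duplicated(seqs)
  log[["duplicate_collapse"]] <- sum(dup)
  seqs <- seqs[!dup]; lin <- lin[!dup, , drop = FALSE]
  empty_db_check(seqs, log)

  # Leave-one-out self-consistency. With the sequence withheld, its own
  # label at deep ranks (e.g. a singleton species) can never be reproduced,
  # so consistency is only required down to the deepest rank whose recorded
  # label is still attainable from the remaining training set; a confident
  # disagreement at any attainable rank discards the entry.
  consistent <- vapply(seq_along(seqs), function(i) {
    train <- lin[-i, , drop = FALSE]
    attainable <- 0L
    for (r in RANKS) {
      if (lin[[r]][i] %in% train[[r]]) attainable <- attainable + 1L else break
    }
    if (attainable == 0L) return(TRUE)
    db_i <- new_ref_db(seqs[-i], train)
    assigned <- classify_rdp(seqs[[i]], db_i, confidence = confidence,
                             bootstraps = bootstraps,
                             seed = child_seed(seed, i))
    own <- unlist(lin[i, RANKS])
    labs <- unclass(assigned)
    depth <- min(length(labs), attainable)
    depth == 0L || all(labs[seq_len(depth)] == own[seq_len(depth)])
  }, logical(1))
  log[["self_consistency"]] <- sum(!consistent)
  seqs <- seqs[consistent]; lin <- lin[consistent, , drop = FALSE]
  empty_db_check(seqs, log)

  recs <- marker_records(gene_id = names(seqs), sample_id = "db",
                         sequence = unname(seqs), score = 100)
  cl <- cluster_representatives(recs, identity = species_identity)
  rep_ids <- cl$centroids$gene_id
  log[["species_clustering"]] <- length(seqs) - length(rep_ids)
  pick <- match(rep_ids, names(seqs))
  new_ref_db(seqs[pick], lin[pick, , drop = FALSE], curation_log = log)
}

empty_db_check <- function(seqs, log) {
  if (length(seqs) == 0L) {
    abort("all sequences discarded during curation (",
          paste(sprintf("%s=%d", names(log), log), collapse = ", "), ")",
          class = "springcomm_empty_db_error")
  }
}

new_ref_db <- function(sequences, lineages, curation_log = NULL) {
  structure(list(sequences = sequences, lineages = lineages,
                 curation_log = curation_log,
                 word_size = WORD_SIZE,
                 index = build_word_index(sequences)),
            class = "curated_ref_db")
}

#' Construct a reference database without curation
#'
#' Wraps a labelled marker set directly into the classifier's database
#' structure (k-mer index included), skipping the curation filters.
#'
#' @param refs A `marker_refs` object.
#' @return A `curated_ref_db`.
#' @export
as_ref_db <- function(refs) {
  new_ref_db(refs$sequences, refs$lineages)
}

#' @export
print.curated_ref_db <- function(x, ...) {
  cat("curated_ref_db:", length(x$sequences), "representatives,",
      length(x$index$dict), "indexed", paste0(x$word_size, "-mers"), "\n")
  if (!is.null(x$curation_log)) {
    cat("curation log:", paste(sprintf("%s=%d", names(x$curation_log),
                                       x$curation_log), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Naive Bayes taxonomy classification with bootstrap confidence
#'
#' Word-based (8-mer) naive Bayes classification in the RDP style: the
#' full-word-set winner fixes the candidate lineage; each of `bootstraps`
#' replicates scores a random subsample of `ceiling(W/8)` of the query's `W`
#' unique words (with replacement) and votes for its own best reference.
#' Per-rank confidence is the fraction of replicates agreeing with the winner
#' at that rank; the lineage is reported down to the deepest rank with
#' confidence >= `confidence`.
#'
#' @param query Nucleotide sequence (>= 8 nt).
#' @param db A `curated_ref_db`.
#' @param confidence Reporting threshold (default 0.60).
#' @param bootstraps Number of bootstrap replicates (default 100).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `taxonomic_lineage` with per-rank confidences (attribute
#'   `confidence`, all 7 ranks of the winner) and `path = "rdp"`.
#' @export
classify_rdp <- function(query, db, confidence = 0.60, bootstraps = 100,
                         seed = 1) {
  check_sequence(query, "query")
  if (!inherits(db, "curated_ref_db") || length(db$sequences) == 0L) {
    abort("'db' must be a non-empty curated_ref_db")
  }
  check_fraction(confidence, "confidence")
  bootstraps <- check_count(bootstraps, "bootstraps")
  words <- sequence_words(query)
  W <- length(words)
  widx <- match(words, db$index$dict)
  logp <- matrix(log(db$index$prior_unseen / 2), nrow = length(db$sequences),
                 ncol = W)
  seen <- !is.na(widx)
  logp[, seen] <- db$index$logp[, widx[seen], drop = FALSE]

  full_scores <- rowSums(logp)
  winner <- which.max(full_scores)    # deterministic: first max in db order

  s <- ceiling(W / WORD_SIZE)
  votes <- with_seed(seed, {
    counts <- vapply(seq_len(bootstraps), function(b) {
      tabulate(sample.int(W, s, replace = TRUE), nbins = W)
    }, numeric(W))
    scores <- logp %*% counts              # refs x bootstraps
    max.col(t(scores), ties.method = "first")
  })

  lin <- db$lineages
  win_lab <- unlist(lin[winner, RANKS])
  conf <- vapply(RANKS, function(r) {
    mean(lin[[r]][votes] == win_lab[[r]])
  }, numeric(1))
  depth <- match(FALSE, conf >= confidence, nomatch = length(RANKS) + 1L) - 1L
  new_lineage(win_lab[seq_len(depth)], confidence = conf, path = "rdp")
}

#' Lowest-concordant-rank assignment from top identity hits
#'
#' Ranks the database by global-alignment identity to the query, takes the
#' top `min(k, |db|)` hits (identity ties at the k-th position are all
#' included), and reports the deepest rank at which all selected hits share a
#' single label, with all shallower ranks filled.
#'
#' @param query Nucleotide sequence.
#' @param db A `curated_ref_db`.
#' @param k Number of top hits (default 5).
#' @return A `taxonomic_lineage` with `path = "lca"`.
#' @export
assign_lca_topk <- function(query, db, k = 5) {
  check_sequence(query, "query")
  if (!inherits(db, "curated_ref_db") || length(db$sequences) == 0L) {
    abort("'db' must be a non-empty curated_ref_db")
  }
  k <- check_count(k, "k")
  ids <- identity_to_refs(query, db$sequences)
  k_eff <- min(k, length(ids))
  cut <- sort(ids, decreasing = TRUE)[k_eff]
  sel <- which(ids >= cut)    # includes all hits tied with the k-th
  lin <- db$lineages[sel, , drop = FALSE]
  depth <- 0L
  for (r in RANKS) {
    if (length(unique(lin[[r]])) == 1L) depth <- depth + 1L else break
  }
  labs <- if (depth > 0L) unlist(lin[1, RANKS[seq_len(depth)]]) else character(0)
  new_lineage(labs, path = "lca")
}

#' Assign taxonomy with the classifier-then-LCA fallback chain
#'
#' Runs [classify_rdp()]; if the result cannot be assigned at phylum level or
#' deeper (phylum confidence below the threshold), falls back to
#' [assign_lca_topk()]. The returned lineage records which path produced it
#' (attribute `path`, `"rdp"` or `"lca"`).
#'
#' @inheritParams classify_rdp
#' @param k Top-hit count for the fallback (default 5).
#' @return A `taxonomic_lineage`.
#' @export
assign_taxonomy <- function(query, db, confidence = 0.60, k = 5,
                            bootstraps = 100, seed = 1) {
  rdp <- classify_rdp(query, db, confidence = confidence,
                      bootstraps = bootstraps, seed = seed)
  if (length(unclass(rdp)) >= 2L) return(rdp)
  assign_lca_topk(query, db, k = k)
}
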