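# Marker identification: screening thresholds, alignment identity, reference
# confirmation, and greedy centroid clustering.

test_that("screening applies strict score and length removals", {
  recs <- marker_records(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    sample_id = "s1",
    sequence = strrep("ACGT", 50),
    score = c(39.9, 40, 10, 40, 500),
    length_aa = c(100, 60, 60, 60, 59)
  )
  kept <- screen_candidates(recs)
  # 39.9 fails score; among {10,40,500}x{60,60,59} only score-40/len-60 pass
  expect_setequal(kept$gene_id, c("g2", "g4"))
  # order preserved
  expect_identical(kept$gene_id, c("g2", "g4"))
  expect_error(screen_candidates(recs, score_min = 0), "positive")
  empty <- recs[0, ]
  expect_equal(nrow(screen_candidates(empty)), 0)
})

test_that("pairwise identity matches hand values and the DP enumeration oracle", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_error(pairwise_identity("ACGN", "ACGT"), "A/C/G/T")
  expect_error(pairwise_identity("", "ACGT"), "non-empty")

  set.seed(42)
  for (i in 1:20) {
    a <- random_seq(sample(3:8, 1))
    b <- random_seq(sample(3:8, 1))
    id <- pairwise_identity(a, b)
    expect_true(any(abs(oracle_nw_identities(a, b) - id) < 1e-12),
                info = paste(a, b))
    expect_equal(id, pairwise_identity(b, a))
  }
  # spec example: unequal lengths against the exhaustive oracle
  expect_true(any(abs(oracle_nw_identities("ACGTACGT", "ACGT") -
                        pairwise_identity("ACGTACGT", "ACGT")) < 1e-12))
})

test_that("confirmation keeps records by best reference identity", {
  refs <- fx_refs()
  recs <- marker_records(
    gene_id = c("hit", "junk"),
    sample_id = "s1",
    sequence = c(refs$sequences[[1]], random_seq(900)),
    score = c(100, 100)
  )
  out <- confirm_markers(recs, refs, min_identity = 0.60)
  expect_identical(out$gene_id, "hit")
  expect_equal(out$best_identity, 1.0)

  empty <- recs[0, ]
  class(empty) <- c("marker_records", "data.frame")
  expect_equal(nrow(confirm_markers(empty, refs)), 0)
  expect_error(confirm_markers(recs, character(0)),
               class = "springcomm_config_error")
})

test_that("identical sequences collapse to one cluster; ties are deterministic", {
  recs <- marker_records(paste0("g", 1:3), "s1", rep(strrep("ACGT", 100), 3),
                         score = 100)
  cl <- cluster_representatives(recs)
  expect_equal(nrow(cl$centroids), 1)
  expect_equal(nrow(cl$clusters), 3)
  # equal-length founders: lexicographic gene_id breaks the tie
  s1 <- random_seq(400)
  set.seed(1); s2 <- mutate_fraction(s1, 0.2)  # distinct cluster
  tie <- marker_records(c("b", "a"), "s1", c(s1, s2), score = 100)
  c1 <- cluster_representatives(tie)
  c2 <- cluster_representatives(tie)
  expect_identical(c1$clusters, c2$clusters)
  expect_setequal(c1$centroids$gene_id, c("a", "b"))
})

test_that("well-separated planted clusters match the single-linkage oracle", {
  set.seed(7)
  base <- replicate(3, random_seq(300))
  seqs <- unlist(lapply(1:3, function(g) {
    c(base[g], vapply(1:3, function(k) mutate_fraction(base[g], 0.003), ""))
  }))
  recs <- marker_records(sprintf("g%02d", seq_along(seqs)), "s1", seqs,
                         score = 100)
  cl <- cluster_representatives(recs, identity = 0.99)
  expect_equal(nrow(cl$centroids), 3)
  oracle <- oracle_single_linkage(seqs, 0.99)
  memb <- stats::setNames(cl$clusters$centroid_id, cl$clusters$member_id)
  got <- memb[recs$gene_id]
  expect_equal(length(unique(paste(got, oracle))), 3)  # partitions coincide
})

test_that("partition, monotonicity and exact-equality-grouping properties hold", {
  set.seed(11)
  seqs <- c(replicate(6, random_seq(120)),
            rep(random_seq(120), 2))  # includes exact duplicates
  recs <- marker_records(sprintf("g%02d", seq_along(seqs)), "s1", seqs,
                         score = 100)
  n_prev <- 0
  for (th in c(0.5, 0.8, 0.99, 1.0)) {
    cl <- cluster_representatives(recs, identity = th)
    # partition property
    expect_setequal(cl$clusters$member_id, recs$gene_id)
    expect_false(anyDuplicated(cl$clusters$member_id) > 0)
    # raising the threshold never decreases cluster count
    expect_gte(nrow(cl$centroids), n_prev)
    n_prev <- nrow(cl$centroids)
  }
  # at identity 1.0 clusters equal exact-equality groups
  cl1 <- cluster_representatives(recs, identity = 1.0)
  eq_groups <- as.integer(factor(seqs))
  memb <- stats::setNames(cl1$clusters$centroid_id, cl1$clusters$member_id)
  expect_equal(length(unique(paste(memb[recs$gene_id], eq_groups))),
               length(unique(eq_groups)))
})
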