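# Synthetic spring generator: taxonomy trees, rank-structured marker
# divergence, and planted ground truth in the simulated survey.

test_that("reference taxonomy is a valid deterministic tree", {
  t1 <- make_reference_taxonomy(3, 30, seed = 1)
  t2 <- make_reference_taxonomy(3, 30, seed = 1)
  expect_identical(t1, t2)
  expect_true(validate_taxonomy(t1))
  expect_equal(nrow(t1$lineages), 30)
  expect_equal(length(unique(t1$lineages$phylum)), 3)

  t3 <- make_reference_taxonomy(3, 30, seed = 2)
  expect_false(identical(t1$lineages$species, t3$lineages$species) &&
                 identical(t1$lineages$genus, t3$lineages$genus))
  expect_true(validate_taxonomy(t3))

  # degenerate single-lineage tree
  t4 <- make_reference_taxonomy(1, 1, seed = 7)
  expect_equal(nrow(t4$lineages), 1)
  expect_true(validate_taxonomy(t4))

  expect_error(make_reference_taxonomy(0, 5, seed = 1), "n_phyla")
  expect_error(make_reference_taxonomy(5, 3, seed = 1), "n_species")
})

test_that("marker references realize rank-structured divergence", {
  refs <- fx_refs()
  lin <- fx_taxonomy()$lineages
  idm <- fx_ref_identity()
  same <- function(rank) outer(lin[[rank]], lin[[rank]], `==`)
  ut <- upper.tri(idm)
  genus_pairs <- same("genus") & ut
  family_pairs <- same("family") & !same("genus") & ut
  order_pairs <- same("order") & !same("family") & ut
  expect_gt(mean(idm[genus_pairs]), mean(idm[family_pairs]))
  expect_gt(mean(idm[family_pairs]), mean(idm[order_pairs]))

  # same-genus realized identity near the planted sibling identity
  expect_true(all(abs(idm[genus_pairs] -
                        fx_taxonomy()$sibling_identity[["genus"]]) < 0.03))
})

test_that("two same-genus species at sibling identity 0.97 land in [0.94, 1]", {
  si <- default_sibling_identity()
  si["genus"] <- 0.97
  si["species"] <- 0.985
  tax <- make_reference_taxonomy(1, 2, seed = 5, sibling_identity = si)
  # force both species into one genus (copy the full upper lineage so the
  # tree invariant is preserved)
  upper <- c("phylum", "class", "order", "family", "genus")
  tax$lineages[2, upper] <- tax$lineages[1, upper]
  refs <- synthesize_marker_references(tax, gene_length = 900, seed = 5)
  id <- pairwise_identity(refs$sequences[[1]], refs$sequences[[2]])
  expect_gte(id, 0.94)
  expect_lte(id, 1.0)
  expect_equal(pairwise_identity(refs$sequences[[1]], refs$sequences[[1]]), 1.0)

  r2 <- synthesize_marker_references(tax, gene_length = 900, seed = 5)
  expect_identical(refs$sequences, r2$sequences)
  expect_error(synthesize_marker_references(tax, gene_length = 2, seed = 1),
               "gene_length")
})

test_that("simulated survey carries consistent planted ground truth", {
  ds <- fx_dataset()
  # composition conservation
  expect_true(all(abs(colSums(ds$truth$composition) - 1) < 1e-9))

  # planted bin quality is realized exactly by the marker inventories
  for (b in ds$bins) {
    q <- estimate_quality(b)
    tr <- ds$truth$bin_quality[ds$truth$bin_quality$bin_id == b$bin_id, ]
    expect_equal(q$completeness, tr$true_completeness)
    expect_equal(q$contamination, tr$true_contamination)
    # zero planted contamination -> no duplicated single-copy markers
    if (tr$true_contamination == 0) expect_true(all(b$markers == 1))
  }

  # every planted depth outlier sits outside the IQR fences and is removed
  # (the rule may additionally catch extreme draws from the core depths)
  for (b in ds$bins) {
    planted <- ds$truth$outlier_scaffolds[[b$bin_id]]
    res <- filter_depth_outliers(b)
    expect_true(all(planted %in% res$removed$scaffold_id))
  }
})

test_that("deep sampling recovers the planted composition within 2 points", {
  tax <- fx_taxonomy()
  ds <- simulate_springs(tax, spring_scenario(tax, n_samples = 4,
                                              reads_per_sample = 1e5,
                                              seed = 404))
  counts <- ds$read_counts
  for (s in unique(counts$sample_id)) {
    rc <- counts[counts$sample_id == s, ]
    mat <- matrix(rc$read_count, ncol = 1,
                  dimnames = list(rc$gene_id, s))
    lens <- stats::setNames(rep(ds$gene_length, nrow(rc)), rc$gene_id)
    ab <- marker_abundance(mat, lens)$abundance[, 1]
    sp <- ds$truth$gene_map$species_id[match(rc$gene_id,
                                             ds$truth$gene_map$gene_id)]
    est <- tapply(ab, sp, sum)
    planted <- ds$truth$composition[names(est), s]
    expect_lt(max(abs(est - planted)), 0.02)
  }
})

test_that("fixed seeds give byte-identical written outputs", {
  tax <- make_reference_taxonomy(2, 8, seed = 11)
  sc <- spring_scenario(tax, n_samples = 4, reads_per_sample = 5e3, seed = 11)
  d1 <- file.path(tempdir(), "springs_a")
  d2 <- file.path(tempdir(), "springs_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_spring_dataset(simulate_springs(tax, sc), d1)
  write_spring_dataset(simulate_springs(tax, sc), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})

test_that("invalid compositions are rejected", {
  tax <- make_reference_taxonomy(2, 8, seed = 11)
  sc <- spring_scenario(tax, n_samples = 4, seed = 11)
  sc$composition[1, 1] <- sc$composition[1, 1] + 0.5
  expect_error(simulate_springs(tax, sc), "sum to 1")
})
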