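# Bin curation (IQR depth rule), quality estimation, the medium-quality
# gate, k-mer ANI, and greedy dereplication.

mk_bin <- function(depths, id = "b1", seqs = NULL, markers = integer(0),
                   is_dpann = FALSE) {
  n <- length(depths)
  genome_bin(id, "s1",
             data.frame(scaffold_id = sprintf("%s_c%02d", id, seq_len(n)),
                        length_bp = rep(1000, n), depth = depths,
                        sequence = if (is.null(seqs)) rep(NA_character_, n)
                                   else seqs,
                        stringsAsFactors = FALSE),
             markers = markers, is_dpann = is_dpann)
}

test_that("IQR depth filtering matches hand computation and edge cases", {
  res <- filter_depth_outliers(mk_bin(c(10, 11, 12, 13, 100)))
  # Q1 = 11, Q3 = 13, fences [8, 16]: only the depth-100 scaffold leaves
  expect_equal(res$removed$depth, 100)
  expect_equal(unname(attr(res$removed, "fences")[c("q1", "q3")]), c(11, 13))
  expect_equal(nrow(res$bin$scaffolds), 4)

  # equal depths: IQR = 0, nothing removed
  res2 <- filter_depth_outliers(mk_bin(rep(7, 6)))
  expect_equal(nrow(res2$removed), 0)

  # single scaffold unchanged
  res3 <- filter_depth_outliers(mk_bin(42))
  expect_equal(nrow(res3$removed), 0)
  expect_error(filter_depth_outliers(mk_bin(numeric(0))), "no scaffolds")
})

test_that("completeness/contamination formulas and tiers are exact", {
  sets <- archaeal_marker_sets()
  # DPANN bin: 36 of 48 markers single-copy -> 75% / 0%
  b <- mk_bin(rep(10, 5), markers = stats::setNames(rep(1L, 36),
                                                    sets$dpann48[1:36]),
              is_dpann = TRUE)
  q <- estimate_quality(b)
  expect_equal(q$completeness, 75)
  expect_equal(q$contamination, 0)
  expect_identical(q$marker_set, "dpann48")

  # all 48 present, 4 duplicated -> contamination 100*4/48
  mk <- stats::setNames(rep(1L, 48), sets$dpann48)
  mk[1:4] <- 2L
  q2 <- estimate_quality(mk_bin(rep(10, 5), markers = mk, is_dpann = TRUE))
  expect_equal(q2$contamination, 100 * 4 / 48)
  expect_identical(q2$tier, "medium")

  expect_error(estimate_quality(mk_bin(5, markers = c(NOPE = 1L))),
               "unknown marker")
})

test_that("the quality gate uses strict boundaries", {
  mk_report <- function(comp, cont) {
    structure(list(bin_id = "x", completeness = comp, contamination = cont,
                   marker_set = "standard", scaffold_count = 1,
                   passes_gate = NA, tier = "medium"),
              class = "quality_report")
  }
  expect_false(quality_gate(mk_report(50.0, 5.0)))
  expect_true(quality_gate(mk_report(50.1, 9.9)))
  expect_false(quality_gate(mk_report(95.0, 10.0)))
  # a median-quality genome (89.6% / 0.8%) passes comfortably
  expect_true(quality_gate(mk_report(89.6, 0.8)))
})

test_that("k-mer ANI behaves at the identity, divergence and random limits", {
  set.seed(5)
  g <- replicate(8, random_seq(2000))
  a <- mk_bin(rep(10, 8), id = "a", seqs = g)
  expect_equal(estimate_ani(a, a), 1.0)

  g2 <- vapply(g, function(s) mutate_fraction(s, 0.01), "")
  b <- mk_bin(rep(10, 8), id = "b", seqs = unname(g2))
  ani <- estimate_ani(a, b)
  expect_gte(ani, 0.985)
  expect_lte(ani, 0.995)
  expect_equal(ani, estimate_ani(b, a))

  r <- mk_bin(rep(10, 8), id = "r", seqs = replicate(8, random_seq(2000)))
  expect_lt(estimate_ani(a, r), 0.8)
  expect_error(estimate_ani(mk_bin(5), a), "sequence content")
})

test_that("dereplication recovers planted strain groups and is idempotent", {
  sim <- simulate_strain_bins(n_groups = 3, bins_per_group = 3, seed = 77)
  dr <- dereplicate(sim$bins, sim$reports)
  expect_length(dr$representatives, 3)
  # each representative is the top-scoring member of its group
  for (g in unique(sim$truth$group)) {
    members <- sim$truth[sim$truth$group == g, ]
    best <- members$bin_id[which.max(members$score)]
    expect_true(best %in% dr$representatives)
  }
  # idempotence: dereplicating the representatives returns them unchanged
  reps <- sim$bins[dr$representatives]
  dr2 <- dereplicate(reps, sim$reports[dr$representatives])
  expect_setequal(dr2$representatives, dr$representatives)

  # score ordering: of two identical bins the higher-scoring one represents
  two <- sim$bins[c("G01_B01", "G01_B02")]
  two[["G01_B02"]]$scaffolds$sequence <- two[["G01_B01"]]$scaffolds$sequence
  reps2 <- list(structure(list(bin_id = "G01_B01", completeness = 90,
                               contamination = 0), class = "quality_report"),
                structure(list(bin_id = "G01_B02", completeness = 80,
                               contamination = 0), class = "quality_report"))
  dr3 <- dereplicate(two, reps2)
  expect_identical(dr3$representatives, "G01_B01")
})
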