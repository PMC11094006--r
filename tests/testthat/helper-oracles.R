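# Independent oracles used to check the implementation. These deliberately
# use brute force / enumeration, never the code paths they verify.

# All global alignments of a and b, enumerated recursively (short strings
# only). Returns the set of identities achieved by maximum-score alignments
# under match +1, mismatch -1, gap -2.
oracle_nw_identities <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  results <- list()
  recurse <- function(i, j, score, matches, cols) {
    if (i > length(av) && j > length(bv)) {
      results[[length(results) + 1]] <<- c(score, matches, cols)
      return()
    }
    if (i <= length(av) && j <= length(bv)) {
      m <- av[i] == bv[j]
      recurse(i + 1, j + 1, score + if (m) 1 else -1, matches + m, cols + 1)
    }
    if (i <= length(av)) recurse(i + 1, j, score - 2, matches, cols + 1)
    if (j <= length(bv)) recurse(i, j + 1, score - 2, matches, cols + 1)
  }
  recurse(1, 1, 0, 0, 0)
  m <- do.call(rbind, results)
  best <- max(m[, 1])
  unique(m[m[, 1] == best, 2] / m[m[, 1] == best, 3])
}

# single-linkage grouping at an identity threshold via union-find
oracle_single_linkage <- function(seqs, threshold) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && pairwise_identity(seqs[i], seqs[j]) >= threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# hand implementation of linear-interpolation (type 7) quartiles
oracle_quartile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_iqr_keep <- function(depths) {
  q1 <- oracle_quartile(depths, 0.25)
  q3 <- oracle_quartile(depths, 0.75)
  iqr <- q3 - q1
  depths >= q1 - 1.5 * iqr & depths <= q3 + 1.5 * iqr
}

# ANOSIM R statistic computed from first principles (midranks)
oracle_anosim_R <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  dvals <- dmat[pairs]
  rk <- rank(dvals)                     # midranks
  between <- groups[pairs[, 1]] != groups[pairs[, 2]]
  M <- n * (n - 1) / 2
  (mean(rk[between]) - mean(rk[!between])) / (M / 2)
}

# exact permutation distribution of R for small n (all label arrangements)
oracle_anosim_exact_p <- function(dmat, groups) {
  n <- length(groups)
  g1 <- which(groups == unique(groups)[1])
  combos <- utils::combn(n, length(g1))
  obs <- oracle_anosim_R(dmat, groups)
  rs <- apply(combos, 2, function(idx) {
    g <- rep(unique(groups)[2], n)
    g[idx] <- unique(groups)[1]
    oracle_anosim_R(dmat, g)
  })
  mean(rs >= obs - 1e-12)
}

# deepest rank on which a set of lineage rows concords
oracle_lca_depth <- function(lineage_df) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  depth <- 0
  for (r in ranks) {
    if (length(unique(lineage_df[[r]])) == 1) depth <- depth + 1 else break
  }
  depth
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_fraction <- function(seq, frac) {
  chars <- strsplit(seq, "")[[1]]
  k <- max(1L, round(frac * length(chars)))
  idx <- sample(length(chars), k)
  chars[idx] <- vapply(chars[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  paste(chars, collapse = "")
}
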