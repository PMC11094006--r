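# Co-occurrence network inference among rMAGs in Archaea-dominant springs:
# prevalence filtering, SparCC basis correlations for compositional counts,
# bootstrap pseudo-p values, and thresholded edge construction.

#' Select samples dominated by Archaea
#'
#' Keeps samples whose archaeal fraction strictly exceeds `threshold`
#' (default 0.5).
#'
#' @param archaeal_fraction Named numeric vector, fraction per sample.
#' @param threshold Dominance threshold (default 0.5, strict `>`).
#' @return Character vector of kept sample ids.
#' @export
select_archaea_dominant <- function(archaeal_fraction, threshold = 0.5) {
  check_fraction(threshold, "threshold")
  names(archaeal_fraction)[archaeal_fraction > threshold]
}

#' Prevalence filter on a count table
#'
#' Keeps features present (count > 0) in at least
#' `ceiling(min_fraction * n_samples)` samples; features occurring in fewer
#' than that many samples are excluded.
#'
#' @param counts Feature x sample count matrix (>= 0).
#' @param min_fraction Minimum prevalence fraction (default 0.5).
#' @return Filtered count matrix (possibly 0 rows, with a warning).
#' @export
prevalence_filter <- function(counts, min_fraction = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  check_fraction(min_fraction, "min_fraction")
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts > 0) >= need
  if (!any(keep)) warning("prevalence filter removed every feature")
  counts[keep, , drop = FALSE]
}

# one SparCC estimate from one Dirichlet fraction draw --------------------
# counts: features x samples. Returns correlation matrix.
sparcc_once <- function(counts, exclusion_iterations, exclusion_threshold) {
  p <- nrow(counts)
  # samples are equalized to a fixed effective depth before the posterior
  # draw, so only relative composition enters: rescaling a sample's counts
  # leaves the estimate unchanged
  depth <- 1e4
  alpha <- sweep(counts, 2, colSums(counts), `/`) * depth + 1
  fr <- apply(alpha, 2, rdirichlet1)
  lf <- log(fr)
  # variation matrix t_ij = var(log f_i - log f_j) via the covariance of logs
  cv <- stats::cov(t(lf))
  v <- diag(cv)
  Tmat <- outer(v, v, `+`) - 2 * cv
  diag(Tmat) <- 0

  excluded <- matrix(FALSE, p, p)
  solve_basis <- function() {
    # linear system: t_i. = |S_i| w_i + sum_{j in S_i} w_j, S_i = non-excluded
    A <- matrix(1, p, p)
    A[excluded] <- 0
    diag(A) <- rowSums(!excluded) - 1
    Tm <- Tmat
    Tm[excluded] <- 0
    w <- solve(A, rowSums(Tm))
    pmax(w, 1e-10)   # basis variances must stay positive
  }
  corr_from <- function(w) {
    r <- (outer(w, w, `+`) - Tmat) / (2 * sqrt(outer(w, w)))
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
    r
  }
  w <- solve_basis()
  r <- corr_from(w)
  for (it in seq_len(exclusion_iterations)) {
    cand <- abs(r)
    cand[excluded] <- 0
    diag(cand) <- 0
    m <- which.max(cand)
    if (cand[m] <= exclusion_threshold) break
    ij <- arrayInd(m, dim(cand))
    excluded[ij[1], ij[2]] <- excluded[ij[2], ij[1]] <- TRUE
    w <- solve_basis()
    r <- corr_from(w)
  }
  r
}

#' SparCC basis correlations for compositional count data
#'
#' Implements the SparCC procedure: for each of `n_dirichlet_draws` draws,
#' component fractions are sampled from a per-sample posterior Dirichlet
#' (counts + 1), the log-ratio variation matrix is computed, basis variances
#' are solved from the sparsity-assuming linear system, and correlations are
#' derived; the most strongly correlated pair above `exclusion_threshold` is
#' iteratively excluded from the system (up to `exclusion_iterations` times).
#' The reported matrix is the element-wise median over draws, symmetric with
#' unit diagonal and entries clamped to \[-1, 1\]. Because only fractions
#' enter, rescaling any sample's counts leaves the result unchanged.
#'
#' @param counts Feature x sample count matrix (>= 4 features, >= 10
#'   samples).
#' @param n_dirichlet_draws Number of posterior draws (default 20).
#' @param exclusion_iterations Maximum strong-pair exclusions per draw
#'   (default 10).
#' @param exclusion_threshold Correlation magnitude above which a pair is
#'   excluded from the basis-variance system (default 0.1).
#' @param seed Integer seed.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparcc_correlations <- function(counts, n_dirichlet_draws = 20,
                                exclusion_iterations = 10,
                                exclusion_threshold = 0.1, seed = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 4L) {
    abort("SparCC needs at least 4 features (basis-variance system is ",
          "underdetermined below that)")
  }
  if (ncol(counts) < 10L) abort("SparCC needs at least 10 samples")
  n_dirichlet_draws <- check_count(n_dirichlet_draws, "n_dirichlet_draws")
  with_seed(seed, {
    draws <- lapply(seq_len(n_dirichlet_draws), function(i) {
      sparcc_once(counts, exclusion_iterations, exclusion_threshold)
    })
    r <- apply(simplify2array(draws), c(1, 2), stats::median)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(rownames(counts), rownames(counts))
    r
  })
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' Follows the original SparCC release semantics for "pseudo p-values":
#' generates `B` null datasets by permuting each feature's counts across
#' samples independently (destroying covariance while keeping marginals),
#' recomputes the SparCC correlation matrix for each, and reports the
#' two-sided add-one estimate
#' `p = (1 + #\{|r_null| >= |r_obs|\}) / (1 + B)` per pair. p-values are in
#' (0, 1] and never exactly 0.
#'
#' @param counts Feature x sample count matrix.
#' @param observed_r Observed SparCC correlation matrix.
#' @param B Number of null datasets (default 100).
#' @param seed Integer seed.
#' @param ... Passed to [sparcc_correlations()] (e.g. fewer Dirichlet draws).
#' @return Matrix of pseudo p-values (diagonal `NA`).
#' @export
bootstrap_pvalues <- function(counts, observed_r, B = 100, seed = 1, ...) {
  counts <- as.matrix(counts)
  B <- check_count(B, "B")
  exceed <- matrix(0, nrow(counts), nrow(counts))
  for (b in seq_len(B)) {
    null_counts <- with_seed(child_seed(seed, b), {
      t(apply(counts, 1, sample))
    })
    r_null <- sparcc_correlations(null_counts, seed = child_seed(seed, B + b),
                                  ...)
    exceed <- exceed + (abs(r_null) >= abs(observed_r))
  }
  p <- (1 + exceed) / (1 + B)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed_r)
  p
}

#' Build a co-occurrence network from correlation and p-value matrices
#'
#' Edges connect pairs with `|r| > r_min` and `p < alpha` (both strict);
#' nodes without any edge are retained as flagged isolates.
#'
#' @param r_matrix Correlation matrix.
#' @param p_matrix Pseudo p-value matrix (conformable).
#' @param node_meta Optional data frame with a `node_id` column plus
#'   annotation columns (e.g. order label, maximum relative abundance).
#' @param r_min Correlation magnitude threshold (default 0.6, strict).
#' @param alpha Significance threshold (default 0.05, strict).
#' @return Object of class `cooccurrence_network`: `nodes` (with `isolate`
#'   flag) and `edges` (`node_i`, `node_j`, `r`, `p`, `sign`; `i < j`).
#' @export
build_network <- function(r_matrix, p_matrix, node_meta = NULL,
                          r_min = 0.6, alpha = 0.05) {
  if (!all(dim(r_matrix) == dim(p_matrix))) abort("matrices must be conformable")
  ids <- rownames(r_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(r_matrix)))
  pairs <- which(upper.tri(r_matrix), arr.ind = TRUE)
  r <- r_matrix[pairs]
  p <- p_matrix[pairs]
  keep <- abs(r) > r_min & p < alpha & !is.na(p)
  edges <- data.frame(node_i = ids[pairs[keep, 1]],
                      node_j = ids[pairs[keep, 2]],
                      r = r[keep], p = p[keep],
                      sign = ifelse(r[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = ids, stringsAsFactors = FALSE)
  if (!is.null(node_meta)) {
    nodes <- merge(nodes, node_meta, by = "node_id", all.x = TRUE, sort = FALSE)
    nodes <- nodes[match(ids, nodes$node_id), , drop = FALSE]
  }
  nodes$isolate <- !(nodes$node_id %in% c(edges$node_i, edges$node_j))
  structure(list(nodes = nodes, edges = edges, r_min = r_min, alpha = alpha),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative ) at |r| >", x$r_min,
      "& p <", x$alpha, "\n")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param network A `cooccurrence_network`.
#' @return An igraph graph (requires the igraph package).
#' @export
as_igraph <- function(network) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("the igraph package is required for as_igraph()")
  }
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}
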