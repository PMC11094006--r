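# Sample grouping by pH/temperature thresholds and community ordination and
# permutation statistics. The statistics themselves are routine and delegate
# to vegan (Bray-Curtis, ANOSIM) and stats (classical scaling, Pearson test);
# this module fixes the contracts: threshold boundaries, add-one permutation
# p-values, and positive-eigenvalue-only PCoA.

#' Assign pH and temperature classes to samples
#'
#' pH classes: acidic (pH < 5.5), neutral (5.5 <= pH < 8.5), alkaline
#' (pH >= 8.5). Temperature classes: mesothermal (< 60 degC), thermal
#' (60 <= T < 80), hyperthermal (>= 80). Boundary values fall in the upper
#' class (pH 5.5 is neutral, 8.5 alkaline; 60 degC thermal, 80 hyperthermal).
#' Samples missing either value are flagged ungrouped (`NA` classes).
#'
#' @param metadata Data frame with columns `sample_id`, `pH`,
#'   `temperature_C`, and optionally `season`.
#' @return Data frame `sample_id`, `ph_class`, `temp_class`, `season`,
#'   `ungrouped`.
#' @examples
#' assign_groups(data.frame(sample_id = "DRTY-16", pH = 2.11,
#'                          temperature_C = 38.1))
#' @export
assign_groups <- function(metadata) {
  ph <- metadata$pH
  tc <- metadata$temperature_C
  if (any(ph < 0 | ph > 14, na.rm = TRUE)) abort("pH must lie in [0, 14]")
  if (any(tc < 0, na.rm = TRUE)) abort("temperature must be >= 0 degC")
  ph_class <- ifelse(is.na(ph), NA_character_,
                     ifelse(ph < 5.5, "acidic",
                            ifelse(ph < 8.5, "neutral", "alkaline")))
  temp_class <- ifelse(is.na(tc), NA_character_,
                       ifelse(tc < 60, "mesothermal",
                              ifelse(tc < 80, "thermal", "hyperthermal")))
  data.frame(sample_id = metadata$sample_id,
             ph_class = ph_class, temp_class = temp_class,
             season = if ("season" %in% names(metadata)) metadata$season
                      else NA_character_,
             ungrouped = is.na(ph_class) | is.na(temp_class),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over features, computed with
#' [vegan::vegdist()]. Values lie in \[0, 1\]; samples with all-zero profiles
#' are rejected.
#'
#' @param matrix Feature x sample abundance matrix (non-negative).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (any(matrix < 0)) abort("abundances must be non-negative")
  zero <- colSums(matrix) == 0
  if (any(zero)) {
    abort("all-zero sample(s): ", paste(colnames(matrix)[zero], collapse = ", "))
  }
  vegan::vegdist(t(matrix), method = "bray")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix (Gower) and eigendecomposes it
#' via [stats::cmdscale()]. Coordinates are returned for positive eigenvalues
#' only; negative eigenvalues (possible for non-Euclidean input such as
#' Bray-Curtis) are dropped, not corrected, and their magnitudes reported.
#'
#' @param d A `dist` object or symmetric distance matrix (>= 3 samples).
#' @return List with `points` (samples x axes), `eig` (positive eigenvalues,
#'   descending), `variance_explained` (fractions of the positive-eigenvalue
#'   total), and `negative_eig`.
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) abort("PCoA needs at least 3 samples")
  # cmdscale warns when fewer than k eigenvalues are positive; dropping the
  # non-positive part is this function's documented behaviour
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-12
  pos <- which(eig > tol)
  pts <- sc$points[, seq_along(pos), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_along(pos))
  list(points = pts, eig = eig[pos],
       variance_explained = eig[pos] / sum(eig[pos]),
       negative_eig = eig[eig < -tol])
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test comparing between-group and within-group
#' distances: `R = (mean rank between - mean rank within) / (M / 2)` with
#' `M = n(n-1)/2` and midranks for ties; the p-value uses the add-one
#' estimator `(1 + #permuted R >= observed) / (1 + permutations)`. Delegates
#' to [vegan::anosim()] under a locally fixed seed.
#'
#' @param d A `dist` object over samples.
#' @param groups Grouping vector (>= 2 groups with >= 2 members each).
#' @param permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List with `R`, `p`, `permutations`.
#' @export
anosim <- function(d, groups, permutations = 999, seed = 1) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) abort("need at least 2 groups")
  if (any(sizes < 2L)) {
    abort("every group needs >= 2 members (", paste(names(sizes)[sizes < 2],
                                                    collapse = ", "), ")")
  }
  permutations <- check_count(permutations, "permutations")
  fit <- with_seed(seed, vegan::anosim(d, groups, permutations = permutations))
  list(R = unname(fit$statistic), p = fit$signif, permutations = permutations)
}

#' Pearson correlation test
#'
#' Sample correlation with a two-sided p-value from the t-distribution with
#' n - 2 degrees of freedom ([stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("correlation undefined for zero-variance input")
  }
  fit <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(fit$estimate), p = fit$p.value)
}
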