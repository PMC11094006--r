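# Synthetic spring-community generator: produces every input the pipeline
# consumes (per-sample marker genes with search scores and read counts,
# scaffold depths, genome bins with planted completeness/contamination and
# depth outliers, annotation tables with planted pathway content, sample
# metadata) together with the planted ground truth, so every downstream
# stage is testable without external data.

CAZY_POOL <- c("GH1", "GH5", "GH13", "GH57", "GT2", "GT4", "CE1", "CE4",
               "PL1", "AA3", "CBM2", "CBM48")

#' Define a synthetic spring scenario
#'
#' Draws the study conditions for one synthetic multi-sample spring survey:
#' sample metadata (pH split between acidic and alkaline springs,
#' temperatures spanning mesothermal to hyperthermal, alternating seasons),
#' a planted community composition per sample (Dirichlet-distributed, with
#' species preferring acidic or alkaline springs so the two groups differ
#' compositionally), planted bin specifications (true completeness and
#' contamination in marker units, depth-outlier counts), and planted pathway
#' and CAZyme content per species.
#'
#' @param taxonomy A `reference_taxonomy`.
#' @param n_samples Number of samples (default 20, split between acidic and
#'   alkaline springs).
#' @param reads_per_sample Marker-recruited reads per sample (default 1e5).
#' @param seed Integer seed.
#' @param pathways A `pathway_set` used to plant functional content.
#' @return Object of class `spring_scenario`.
#' @export
spring_scenario <- function(taxonomy, n_samples = 20, reads_per_sample = 1e5,
                            seed = 1, pathways = read_pathway_definitions()) {
  validate_taxonomy(taxonomy)
  n_samples <- check_count(n_samples, "n_samples", min = 4L)
  reads_per_sample <- check_count(reads_per_sample, "reads_per_sample")
  lin <- taxonomy$lineages
  n_sp <- nrow(lin)

  with_seed(child_seed(seed, 1), {
    sample_id <- sprintf("SPR%02d", seq_len(n_samples))
    n_acid <- ceiling(n_samples / 2)
    ph <- c(round(runif(n_acid, 2.0, 5.4), 2),
            round(runif(n_samples - n_acid, 8.5, 9.9), 2))
    metadata <- data.frame(
      sample_id = sample_id, pH = ph,
      temperature_C = round(runif(n_samples, 40, 95), 1),
      season = rep_len(c("winter", "summer"), n_samples),
      stringsAsFactors = FALSE
    )

    # species habitat preference drives the planted group difference
    pref <- sample(c("acidic", "alkaline", "generalist"), n_sp,
                   replace = TRUE, prob = c(0.45, 0.45, 0.10))
    alpha_for <- function(sample_class) {
      ifelse(pref == "generalist", 1.5,
             ifelse(pref == sample_class, 5, 0.1))
    }
    composition <- vapply(seq_len(n_samples), function(s) {
      rdirichlet1(alpha_for(if (ph[s] < 5.5) "acidic" else "alkaline"))
    }, numeric(n_sp))
    dimnames(composition) <- list(lin$species_id, sample_id)

    # one bin per species, originating from the sample where it is most
    # abundant; planted quality in marker units so completeness is exact
    sets <- archaeal_marker_sets()
    is_dpann <- runif(n_sp) < 0.3
    n_expected <- ifelse(is_dpann, length(sets$dpann48), length(sets$standard))
    placed <- vapply(n_expected, function(m) {
      sample(seq(ceiling(0.55 * m), m), 1L)
    }, integer(1))
    extra <- sample(0:3, n_sp, replace = TRUE)
    # plant a completeness failure and a contamination failure to exercise
    # the quality gate downstream
    placed[1] <- floor(0.4 * n_expected[1])
    extra[2] <- ceiling(0.12 * n_expected[2])
    n_scaffolds <- sample(15:40, n_sp, replace = TRUE)
    n_scaffolds[3] <- 210L   # exercises the <200-scaffold pathway cap
    bin_specs <- data.frame(
      bin_id = sprintf("BIN%03d", seq_len(n_sp)),
      species_id = lin$species_id,
      origin_sample = sample_id[apply(composition, 1, which.max)],
      is_dpann = is_dpann,
      markers_expected = n_expected,
      markers_placed = placed,
      extra_copies = extra,
      n_scaffolds = n_scaffolds,
      n_outlier_scaffolds = sample(0:2, n_sp, replace = TRUE),
      has_rps3 = runif(n_sp) > 0.1,
      stringsAsFactors = FALSE
    )

    status <- matrix(sample(c("complete", "partial", "absent"),
                            n_sp * length(pathways), replace = TRUE,
                            prob = c(0.3, 0.2, 0.5)),
                     nrow = n_sp,
                     dimnames = list(lin$species_id, names(pathways)))
    # acidic-preferring species get fewer CAZy families (echoes the pH
    # patterning of carbohydrate usage in spring communities)
    cazy <- lapply(seq_len(n_sp), function(i) {
      k <- if (pref[i] == "acidic") sample(0:3, 1L) else sample(2:6, 1L)
      sample(CAZY_POOL, k)
    })
    names(cazy) <- lin$species_id

    structure(list(taxonomy = taxonomy, n_samples = n_samples,
                   reads_per_sample = reads_per_sample,
                   metadata = metadata, composition = composition,
                   preference = stats::setNames(pref, lin$species_id),
                   bin_specs = bin_specs, pathway_status = status,
                   pathways = pathways, cazy = cazy,
                   read_length = 150L, seed = seed),
              class = "spring_scenario")
  })
}

#' @export
print.spring_scenario <- function(x, ...) {
  cat("spring_scenario:", x$n_samples, "samples,",
      nrow(x$composition), "species,", x$reads_per_sample,
      "marker reads/sample\n")
  invisible(x)
}

validate_scenario <- function(scenario) {
  if (!inherits(scenario, "spring_scenario")) abort("not a spring_scenario")
  sums <- colSums(scenario$composition)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("per-sample compositions must sum to 1 (max deviation ",
          format(max(abs(sums - 1))), ")")
  }
  invisible(TRUE)
}

#' Simulate a full synthetic spring dataset
#'
#' Realizes a scenario into the concrete pipeline inputs:
#'
#' * marker reference set (one gene per species, rank-structured divergence);
#' * per-sample candidate marker records: one sequence variant per planted
#'   species (about 0.5% diverged from its reference) plus three decoys per
#'   sample exercising the screen (a low-score hit, a short translation, and
#'   a random non-marker sequence with a good score);
#' * per-gene read counts drawn multinomially so that expected marker
#'   relative abundance equals the planted composition;
#' * genome bins whose marker inventories realize the planted completeness
#'   and contamination exactly, with depth-outlier scaffolds placed outside
#'   the planted IQR fences;
#' * annotation and metadata tables, and the full ground truth.
#'
#' Fixed seeds give byte-identical outputs (see [write_spring_dataset()]).
#'
#' @param taxonomy A `reference_taxonomy` (must match the scenario's).
#' @param scenario A `spring_scenario`.
#' @return Object of class `spring_dataset`.
#' @export
simulate_springs <- function(taxonomy, scenario) {
  validate_taxonomy(taxonomy)
  validate_scenario(scenario)
  lin <- taxonomy$lineages
  seed <- scenario$seed
  refs <- synthesize_marker_references(taxonomy, gene_length = 900,
                                       seed = child_seed(seed, 2))
  gene_length <- nchar(refs$sequences[[1]])
  # terminal within-species branch: half the species-level JC branch, so a
  # sample variant sits ~0.5% from its reference and two variants of one
  # species remain comfortably inside a 99% identity cluster
  t_within <- jc_branch_length(taxonomy$sibling_identity[["species"]]) / 2

  with_seed(child_seed(seed, 3), {
    comp <- scenario$composition
    samples <- colnames(comp)
    present <- comp > 1e-6
    cand <- list(); counts <- list(); truth_map <- list()
    for (s in samples) {
      sp <- rownames(comp)[present[, s]]
      gid <- sprintf("%s|rps3|%s", s, sp)
      seqs <- vapply(refs$sequences[sp], mutate_jc, "", t = t_within)
      reads <- as.integer(rmultinom(1, scenario$reads_per_sample,
                                    prob = comp[sp, s]))
      recs <- marker_records(
        gene_id = gid, sample_id = s, sequence = unname(seqs),
        score = round(runif(length(sp), 45, 320), 1),
        coverage = reads * scenario$read_length / gene_length
      )
      # decoys: low score, short translation, non-marker sequence
      decoys <- marker_records(
        gene_id = paste0(s, "|decoy|", c("lowscore", "short", "offtarget")),
        sample_id = s,
        sequence = c(mutate_jc(refs$sequences[[sp[1]]], t_within),
                     random_dna(120), random_dna(gene_length)),
        score = c(round(runif(1, 5, 39.5), 1), round(runif(1, 60, 200), 1),
                  round(runif(1, 60, 200), 1)),
        coverage = 0
      )
      cand[[s]] <- rbind(recs, decoys)
      counts[[s]] <- data.frame(gene_id = gid, sample_id = s,
                                read_count = reads, stringsAsFactors = FALSE)
      truth_map[[s]] <- data.frame(gene_id = gid, species_id = sp,
                                   stringsAsFactors = FALSE)
    }
    candidates <- do.call(rbind, cand)
    class(candidates) <- c("marker_records", "data.frame")
    read_counts <- do.call(rbind, counts)
    gene_map <- do.call(rbind, truth_map)
    rownames(candidates) <- rownames(read_counts) <- rownames(gene_map) <- NULL

    sets <- archaeal_marker_sets()
    bins <- lapply(seq_len(nrow(scenario$bin_specs)), function(i) {
      spec <- scenario$bin_specs[i, ]
      make_planted_bin(spec, sets, gene_map, scenario)
    })
    names(bins) <- scenario$bin_specs$bin_id

    annotations <- do.call(rbind, lapply(bins, function(b) b$annotations))
    rownames(annotations) <- NULL

    truth <- list(
      composition = comp,
      gene_map = gene_map,
      bin_quality = data.frame(
        bin_id = scenario$bin_specs$bin_id,
        species_id = scenario$bin_specs$species_id,
        true_completeness = 100 * scenario$bin_specs$markers_placed /
          scenario$bin_specs$markers_expected,
        true_contamination = 100 * scenario$bin_specs$extra_copies /
          scenario$bin_specs$markers_expected,
        stringsAsFactors = FALSE
      ),
      pathway_status = scenario$pathway_status,
      outlier_scaffolds = stats::setNames(
        lapply(bins, function(b) attr(b, "planted_outliers")), names(bins))
    )
    structure(list(refs = refs, candidates = candidates,
                   read_counts = read_counts, bins = bins,
                   annotations = annotations, metadata = scenario$metadata,
                   scenario = scenario, truth = truth,
                   gene_length = gene_length),
              class = "spring_dataset")
  })
}

# Build one genome bin realizing a planted spec: exact marker inventory,
# depth outliers guaranteed outside the IQR fences of the full depth vector.
make_planted_bin <- function(spec, sets, gene_map, scenario) {
  set <- if (spec$is_dpann) sets$dpann48 else sets$standard
  placed_ids <- sample(set, spec$markers_placed)
  markers <- stats::setNames(rep(1L, length(placed_ids)), placed_ids)
  if (spec$extra_copies > 0) {
    dup <- sample(placed_ids, spec$extra_copies)
    markers[dup] <- markers[dup] + 1L
  }

  n_core <- spec$n_scaffolds - spec$n_outlier_scaffolds
  base_depth <- runif(1, 5, 50)
  # uniform band: core depths essentially never breach their own Tukey fences
  core <- round(runif(n_core, 0.85 * base_depth, 1.15 * base_depth), 2)
  depths <- core
  if (spec$n_outlier_scaffolds > 0) {
    mult <- rep_len(c(8, 1 / 50), spec$n_outlier_scaffolds)
    out_d <- round(base_depth * mult, 2)
    # guarantee the planted outliers sit outside the realized fences
    repeat {
      all_d <- c(core, out_d)
      q <- stats::quantile(all_d, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      bad <- out_d >= q[1] - 1.5 * iqr & out_d <= q[2] + 1.5 * iqr
      if (!any(bad)) break
      out_d[bad] <- ifelse(out_d[bad] > base_depth, out_d[bad] * 2,
                           out_d[bad] / 2)
    }
    depths <- c(core, out_d)
  }
  lens <- sample(800:2500, spec$n_scaffolds, replace = TRUE)
  scafs <- data.frame(
    scaffold_id = sprintf("%s_scf%03d", spec$bin_id, seq_len(spec$n_scaffolds)),
    length_bp = lens,
    depth = depths,
    sequence = vapply(lens, random_dna, ""),
    stringsAsFactors = FALSE
  )

  status <- scenario$pathway_status[spec$species_id, ]
  kos <- unlist(lapply(names(status), function(p) {
    req <- scenario$pathways[[p]]
    if (status[[p]] == "complete") req
    else if (status[[p]] == "partial" && length(req) > 1) {
      req[seq_len(sample(length(req) - 1L, 1L))]
    } else character(0)
  }), use.names = FALSE)
  caz <- scenario$cazy[[spec$species_id]]
  n_genes <- length(kos) + length(caz)
  annotations <- if (n_genes > 0) {
    data.frame(
      rmag_id = spec$bin_id,
      gene_id = sprintf("%s_gene%03d", spec$bin_id, seq_len(n_genes)),
      ko = c(kos, rep(NA_character_, length(caz))),
      cazy_family = c(rep(NA_character_, length(kos)), caz),
      scaffold_id = sample(scafs$scaffold_id[seq_len(min(n_core, nrow(scafs)))],
                           n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(rmag_id = character(0), gene_id = character(0),
               ko = character(0), cazy_family = character(0),
               scaffold_id = character(0), stringsAsFactors = FALSE)
  }

  gene_ids <- if (spec$has_rps3) {
    gene_map$gene_id[gene_map$species_id == spec$species_id]
  } else character(0)

  b <- genome_bin(spec$bin_id, spec$origin_sample, scafs, markers = markers,
                  is_dpann = spec$is_dpann, annotations = annotations,
                  gene_ids = gene_ids)
  attr(b, "planted_outliers") <-
    scafs$scaffold_id[seq_len(spec$n_scaffolds) > n_core]
  b
}

#' @export
print.spring_dataset <- function(x, ...) {
  cat("spring_dataset:", length(unique(x$candidates$sample_id)), "samples,",
      nrow(x$candidates), "candidate genes,", length(x$bins), "bins\n")
  invisible(x)
}

#' Write a spring dataset to disk
#'
#' Emits the dataset as plain-text files: `genes.fna` (all candidate genes),
#' `candidates.tsv` (gene_id, sample_id, score), `read_counts.tsv`,
#' `scaffold_depths.tsv` (bin_id, scaffold_id, length_bp, depth),
#' one FASTA per bin under `bins/`, `annotations.tsv`, `metadata.tsv`, a
#' reference FASTA + lineage TSV, and the ground-truth tables under
#' `truth/`. All tables are tab-delimited UTF-8 with '.' decimals; output is
#' byte-identical for a fixed-seed dataset.
#'
#' @param dataset A `spring_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spring_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "bins"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ds <- dataset
  write_fasta(stats::setNames(ds$candidates$sequence, ds$candidates$gene_id),
              file.path(dir, "genes.fna"))
  write_tsv(ds$candidates[, c("gene_id", "sample_id", "score", "length_aa",
                              "coverage")],
            file.path(dir, "candidates.tsv"))
  write_tsv(ds$read_counts, file.path(dir, "read_counts.tsv"))
  depths <- do.call(rbind, lapply(ds$bins, function(b) {
    data.frame(bin_id = b$bin_id, b$scaffolds[, c("scaffold_id", "length_bp",
                                                  "depth")],
               stringsAsFactors = FALSE)
  }))
  rownames(depths) <- NULL
  write_tsv(depths, file.path(dir, "scaffold_depths.tsv"))
  for (b in ds$bins) {
    write_fasta(stats::setNames(b$scaffolds$sequence, b$scaffolds$scaffold_id),
                file.path(dir, "bins", paste0(b$bin_id, ".fna")))
  }
  write_tsv(ds$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(ds$metadata, file.path(dir, "metadata.tsv"))
  write_fasta(ds$refs$sequences, file.path(dir, "reference_markers.fna"))
  write_tsv(ds$refs$lineages, file.path(dir, "reference_lineages.tsv"))
  comp <- data.frame(species_id = rownames(ds$truth$composition),
                     ds$truth$composition, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(comp, file.path(dir, "truth", "composition.tsv"))
  write_tsv(ds$truth$gene_map, file.path(dir, "truth", "gene_map.tsv"))
  write_tsv(ds$truth$bin_quality, file.path(dir, "truth", "bin_quality.tsv"))
  invisible(dir)
}

#' Simulate strain groups of genome bins for dereplication tests
#'
#' Generates `n_groups` unrelated ancestral genomes and, within each group,
#' `bins_per_group` strain bins diverged from the ancestor by
#' `within_divergence` substitutions per site per branch (so within-group ANI
#' is about `1 - 2 * within_divergence` and between-group ANI is near 0).
#' Each bin gets a planted quality report so dRep-style scoring is exercised.
#'
#' @param n_groups Number of strain groups.
#' @param bins_per_group Bins per group.
#' @param within_divergence Per-branch substitution rate (default 0.0025).
#' @param n_scaffolds,scaffold_bp Genome shape per bin.
#' @param seed Integer seed.
#' @return List with `bins`, `reports`, and `truth` (data frame `bin_id`,
#'   `group`, `score`).
#' @export
simulate_strain_bins <- function(n_groups = 3, bins_per_group = 3,
                                 within_divergence = 0.0025,
                                 n_scaffolds = 10, scaffold_bp = 1500,
                                 seed = 1) {
  n_groups <- check_count(n_groups, "n_groups")
  bins_per_group <- check_count(bins_per_group, "bins_per_group")
  with_seed(seed, {
    bins <- list(); truth <- list()
    for (g in seq_len(n_groups)) {
      ancestor <- vapply(seq_len(n_scaffolds), function(i) {
        random_dna(scaffold_bp)
      }, "")
      for (k in seq_len(bins_per_group)) {
        bid <- sprintf("G%02d_B%02d", g, k)
        seqs <- vapply(ancestor, mutate_jc, "", t = within_divergence)
        scafs <- data.frame(
          scaffold_id = sprintf("%s_scf%02d", bid, seq_len(n_scaffolds)),
          length_bp = scaffold_bp,
          depth = round(runif(n_scaffolds, 10, 30), 2),
          sequence = unname(seqs), stringsAsFactors = FALSE
        )
        placed <- sample(30:53, 1L)
        mk <- stats::setNames(rep(1L, placed),
                              sample(archaeal_marker_sets()$standard, placed))
        bins[[bid]] <- genome_bin(bid, "simulated", scafs, markers = mk)
        truth[[bid]] <- data.frame(bin_id = bid, group = g,
                                   stringsAsFactors = FALSE)
      }
    }
    reports <- lapply(bins, estimate_quality)
    truth <- do.call(rbind, truth)
    truth$score <- vapply(reports, function(r) {
      r$completeness - 5 * r$contamination
    }, numeric(1))[truth$bin_id]
    rownames(truth) <- NULL
    list(bins = bins, reports = reports, truth = truth)
  })
}

#' Simulate compositional counts with planted basis correlations
#'
#' Draws per-sample basis abundances from a multivariate log-normal whose
#' correlation matrix is the identity except for the planted feature pairs,
#' closes the composition, and samples multinomial counts at the given
#' depth. Used to exercise SparCC recovery of known correlation structure.
#'
#' @param n_features,n_samples Table shape (defaults 30 x 200).
#' @param planted Data frame `i`, `j`, `rho` of planted basis correlations
#'   (pairs must be disjoint).
#' @param depth Reads per sample (default 5e4).
#' @param log_sd Standard deviation of log basis abundances (default 1).
#' @param seed Integer seed.
#' @return List with `counts` (feature x sample) and `planted`.
#' @export
simulate_correlated_counts <- function(n_features = 30, n_samples = 200,
                                       planted = data.frame(i = 1, j = 2,
                                                            rho = 0.9),
                                       depth = 5e4, log_sd = 1, seed = 1) {
  n_features <- check_count(n_features, "n_features", min = 4L)
  n_samples <- check_count(n_samples, "n_samples", min = 10L)
  if (anyDuplicated(c(planted$i, planted$j))) {
    abort("planted pairs must be disjoint")
  }
  R <- diag(n_features)
  for (k in seq_len(nrow(planted))) {
    R[planted$i[k], planted$j[k]] <- R[planted$j[k], planted$i[k]] <-
      planted$rho[k]
  }
  with_seed(seed, {
    mu <- runif(n_features, 1, 4)
    L <- chol(R)
    z <- mu + log_sd * t(L) %*% matrix(rnorm(n_features * n_samples),
                                       n_features, n_samples)
    w <- exp(z)
    fr <- sweep(w, 2, colSums(w), `/`)
    counts <- vapply(seq_len(n_samples), function(s) {
      rmultinom(1, depth, fr[, s])[, 1]
    }, numeric(n_features))
    dimnames(counts) <- list(sprintf("F%02d", seq_len(n_features)),
                             sprintf("S%03d", seq_len(n_samples)))
    list(counts = counts, planted = planted)
  })
}
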