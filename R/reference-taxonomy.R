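# Synthetic reference taxonomies and rank-structured marker reference sets.
#
# A reference taxonomy is a 7-rank (domain..species) labelled tree in the GTDB
# prefix convention, together with per-rank sibling-identity parameters: the
# expected nucleotide identity between two species whose deepest shared rank is
# the given one. Marker references are simulated down this tree under a
# Jukes-Cantor substitution model so realized pairwise identities follow the
# rank structure.

#' Default sibling-identity parameters
#'
#' Expected sequence identity between two marker genes whose lineages diverge
#' at the given rank (the `species` entry is the within-species identity used
#' for sample-level gene variants). Values strictly decrease from species
#' toward domain, mirroring the loss of marker-gene identity with taxonomic
#' distance.
#'
#' @return Named numeric vector over the seven ranks.
#' @export
default_sibling_identity <- function() {
  c(domain = 0.72, phylum = 0.80, class = 0.845, order = 0.89,
    family = 0.93, genus = 0.965, species = 0.99)
}

#' Generate a synthetic 7-rank reference taxonomy
#'
#' Builds a random labelled taxonomy tree with `n_species` leaves distributed
#' over `n_phyla` phyla (single domain, `d__Archaea`). Intermediate rank sizes
#' are interpolated log-linearly between the phylum and species counts, and
#' every parent receives at least one child, so lineages always form a tree.
#'
#' @param n_phyla Number of phyla (>= 1).
#' @param n_species Number of species (>= n_phyla).
#' @param seed Integer seed; fixed seed gives an identical taxonomy.
#' @param sibling_identity Named numeric vector of per-rank expected sibling
#'   identities, strictly decreasing from species toward domain.
#' @return An object of class `reference_taxonomy`: a list with `lineages`
#'   (data frame, one row per species, columns `domain` .. `species` plus
#'   `species_id`) and `sibling_identity`.
#' @examples
#' tax <- make_reference_taxonomy(3, 30, seed = 1)
#' head(tax$lineages)
#' @export
make_reference_taxonomy <- function(n_phyla, n_species, seed,
                                    sibling_identity = default_sibling_identity()) {
  n_phyla <- check_count(n_phyla, "n_phyla")
  n_species <- check_count(n_species, "n_species")
  if (n_species < n_phyla) abort("'n_species' must be >= 'n_phyla'")
  validate_sibling_identity(sibling_identity)

  with_seed(seed, {
    # rank sizes: log-linear interpolation phylum -> species, kept monotone
    sizes <- round(exp(seq(log(n_phyla), log(n_species), length.out = 6)))
    sizes <- cummax(pmin(pmax(sizes, n_phyla), n_species))
    names(sizes) <- RANKS[-1]

    # surjective parent assignment: each parent gets >= 1 child
    assign_parents <- function(n_child, n_parent) {
      ids <- c(seq_len(n_parent),
               if (n_child > n_parent)
                 sample.int(n_parent, n_child - n_parent, replace = TRUE))
      sample(ids, n_child)
    }

    parent_of <- list()  # per rank below phylum: child index -> parent index
    upper <- RANKS[2:6]  # phylum..genus as parents of class..species
    child <- RANKS[3:7]
    for (i in seq_along(child)) {
      parent_of[[child[i]]] <- assign_parents(sizes[[child[i]]], sizes[[upper[i]]])
    }

    label <- function(rank, i) {
      sprintf("%s%s_%03d", RANK_PREFIX[[rank]],
              paste0(toupper(substr(rank, 1, 1)), substr(rank, 2, nchar(rank))), i)
    }
    # resolve each species' full path
    sp <- seq_len(n_species)
    gen <- parent_of[["species"]][sp]
    fam <- parent_of[["genus"]][gen]
    ord <- parent_of[["family"]][fam]
    cls <- parent_of[["order"]][ord]
    phy <- parent_of[["class"]][cls]
    lineages <- data.frame(
      species_id = sprintf("SP%03d", sp),
      domain = "d__Archaea",
      phylum = label("phylum", phy),
      class = label("class", cls),
      order = label("order", ord),
      family = label("family", fam),
      genus = label("genus", gen),
      species = label("species", sp),
      stringsAsFactors = FALSE
    )
    structure(
      list(lineages = lineages, sibling_identity = sibling_identity,
           n_phyla = n_phyla, n_species = n_species),
      class = "reference_taxonomy"
    )
  })
}

validate_sibling_identity <- function(si) {
  if (!is.numeric(si) || !identical(sort(names(si)), sort(RANKS))) {
    abort("'sibling_identity' must be a numeric vector named by the 7 ranks")
  }
  si <- si[RANKS]
  if (any(si <= 0) || any(si > 1)) abort("sibling identities must lie in (0, 1]")
  if (any(diff(si) <= 0)) {
    abort("sibling identities must strictly decrease from species toward domain")
  }
  invisible(si)
}

#' @export
print.reference_taxonomy <- function(x, ...) {
  cat("reference_taxonomy:", x$n_species, "species in", x$n_phyla, "phyla;",
      length(unique(x$lineages$genus)), "genera,",
      length(unique(x$lineages$order)), "orders\n")
  invisible(x)
}

#' Validate the structural invariants of a reference taxonomy
#'
#' Checks that every lineage has 7 non-empty prefixed ranks and that child
#' labels map to exactly one parent label (tree property).
#'
#' @param taxonomy A `reference_taxonomy`.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (!inherits(taxonomy, "reference_taxonomy")) abort("not a reference_taxonomy")
  lin <- taxonomy$lineages
  for (r in RANKS) {
    v <- lin[[r]]
    if (any(is.na(v) | v == "")) abort("empty labels at rank ", r)
    if (!all(startsWith(v, RANK_PREFIX[[r]]))) abort("bad prefix at rank ", r)
  }
  for (i in 2:7) {
    pairs <- unique(lin[, RANKS[c(i - 1, i)]])
    if (anyDuplicated(pairs[[2]])) {
      abort("rank ", RANKS[i], " label maps to more than one parent")
    }
  }
  validate_sibling_identity(taxonomy$sibling_identity)
  invisible(TRUE)
}

#' Simulate a labelled marker-gene reference set down a taxonomy
#'
#' Generates one nucleotide marker sequence per species by evolving a random
#' root sequence down the taxonomy tree under a Jukes-Cantor substitution
#' model (independent per-site substitutions, no indels). Branch lengths are
#' calibrated from the taxonomy's sibling-identity parameters, so the expected
#' identity between two species diverging at rank r equals
#' `sibling_identity[r]`.
#'
#' @param taxonomy A `reference_taxonomy`.
#' @param gene_length Gene length in bp (>= 3; >= 300 recommended so that
#'   reference-curation length filters are exercisable).
#' @param seed Integer seed.
#' @return An object of class `marker_refs`: list with `sequences` (named
#'   character vector, one per species id) and `lineages` (as in the
#'   taxonomy).
#' @examples
#' tax <- make_reference_taxonomy(2, 6, seed = 1)
#' refs <- synthesize_marker_references(tax, gene_length = 600, seed = 1)
#' nchar(refs$sequences[1])
#' @export
synthesize_marker_references <- function(taxonomy, gene_length = 900, seed) {
  validate_taxonomy(taxonomy)
  gene_length <- check_count(gene_length, "gene_length", min = 3L)
  lin <- taxonomy$lineages
  si <- taxonomy$sibling_identity[RANKS]

  # per-branch divergence of a leaf from its rank-r ancestor
  d <- vapply(si, jc_branch_length, numeric(1))   # decreasing with depth
  with_seed(seed, {
    node_seq <- new.env(parent = emptyenv())
    assign("d__Archaea", random_dna(gene_length), envir = node_seq)
    # evolve rank by rank: edge length = d[parent rank] - d[child rank];
    # species-level node keeps d[species] as residual terminal branch so that
    # within-genus species pairs hit the genus sibling identity.
    for (i in 2:7) {
      child_rank <- RANKS[i]
      parent_rank <- RANKS[i - 1]
      edge <- d[[parent_rank]] - d[[child_rank]]
      pairs <- unique(lin[, c(parent_rank, child_rank)])
      for (j in seq_len(nrow(pairs))) {
        parent <- get(pairs[[parent_rank]][j], envir = node_seq)
        assign(pairs[[child_rank]][j], mutate_jc(parent, edge), envir = node_seq)
      }
    }
    # terminal branch below the species node: residual d[species]
    seqs <- vapply(seq_len(nrow(lin)), function(j) {
      mutate_jc(get(lin$species[j], envir = node_seq), d[["species"]])
    }, character(1))
    names(seqs) <- lin$species_id
    structure(list(sequences = seqs, lineages = lin), class = "marker_refs")
  })
}

#' @export
print.marker_refs <- function(x, ...) {
  cat("marker_refs:", length(x$sequences), "sequences of width",
      nchar(x$sequences[[1]]), "bp\n")
  invisible(x)
}
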