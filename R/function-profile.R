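# Order-level pathway presence, metabolic weight scores, and CAZyme
# summaries over provided annotation tables. Pathway definitions are flat KO
# lists shipped as editable TSV configuration (no KEGG-module boolean logic).

#' Load pathway definitions
#'
#' Reads a TSV with columns `pathway_id`, `name`, `kos` (comma-separated KO
#' identifiers, `K#####`). The bundled default covers a small set of
#' biogeochemically central pathways (Wood-Ljungdahl, DC/4-HB, 3HP/4HB, mcr,
#' DSR, amo, ...) as test configuration, not biology claims.
#'
#' @param path TSV path; default the bundled definitions.
#' @return Named list of class `pathway_set`: pathway id -> character vector
#'   of required KOs; pathway names kept as an attribute.
#' @export
read_pathway_definitions <- function(path = system.file("extdata",
                                                        "pathway_definitions.tsv",
                                                        package = "springcomm")) {
  df <- read_tsv(path)
  kos <- lapply(strsplit(df$kos, ","), trimws)
  names(kos) <- df$pathway_id
  bad <- !vapply(kos, function(k) length(k) > 0 && all(grepl("^K\\d{5}$", k)),
                 logical(1))
  if (any(bad)) {
    abort("invalid or empty KO list for pathway(s): ",
          paste(names(kos)[bad], collapse = ", "),
          class = "springcomm_definition_error")
  }
  structure(kos, names_full = df$name, class = "pathway_set")
}

#' Order-level pathway presence matrix
#'
#' An order contains a pathway (`complete`, code 2) if at least one of its
#' qualifying rMAGs carries every required gene; `partial` (1) if at least one
#' required gene is present anywhere in the order but no single rMAG has all;
#' `absent` (0) otherwise. Only rMAGs with scaffold counts strictly below
#' `max_scaffolds` qualify.
#'
#' @param annotations Data frame `rmag_id`, `gene_id`, `ko` (KO ids; `NA` for
#'   unannotated genes).
#' @param rmag_meta Data frame `rmag_id`, `order`, `n_scaffolds`.
#' @param pathways A `pathway_set` (default bundled definitions).
#' @param max_scaffolds Scaffold-count cap (default 200, strict `<`).
#' @return Integer matrix order x pathway with entries 2/1/0 and attribute
#'   `legend`.
#' @export
pathway_presence <- function(annotations, rmag_meta,
                             pathways = read_pathway_definitions(),
                             max_scaffolds = 200) {
  if (any(lengths(pathways) == 0)) {
    abort("pathway with empty gene set", class = "springcomm_definition_error")
  }
  if (!all(c("rmag_id", "order", "n_scaffolds") %in% names(rmag_meta))) {
    abort("rmag_meta needs columns rmag_id, order, n_scaffolds")
  }
  qualifying <- rmag_meta$rmag_id[rmag_meta$n_scaffolds < max_scaffolds]
  ann <- annotations[annotations$rmag_id %in% qualifying & !is.na(annotations$ko), ,
                     drop = FALSE]
  orders <- sort(unique(rmag_meta$order))
  out <- matrix(0L, nrow = length(orders), ncol = length(pathways),
                dimnames = list(orders, names(pathways)))
  ko_by_rmag <- split(ann$ko, ann$rmag_id)
  order_of <- stats::setNames(rmag_meta$order, rmag_meta$rmag_id)
  for (p in names(pathways)) {
    req <- pathways[[p]]
    complete_rmags <- names(ko_by_rmag)[vapply(ko_by_rmag, function(k) {
      all(req %in% k)
    }, logical(1))]
    partial_rmags <- names(ko_by_rmag)[vapply(ko_by_rmag, function(k) {
      any(req %in% k)
    }, logical(1))]
    out[unique(order_of[partial_rmags]), p] <- 1L
    out[unique(order_of[complete_rmags]), p] <- 2L
  }
  attr(out, "legend") <- c(`2` = "complete", `1` = "partial", `0` = "absent")
  out
}

#' Metabolic weight score per function and sample
#'
#' The MW-score of function `f` in sample `s` is the summed abundance of
#' genomes encoding `f`, normalized by the total over all functions, in
#' percent: a genome encoding several functions contributes to each of their
#' numerators (and to the denominator once per function). Per-sample scores
#' sum to 100.
#'
#' @param fun_map Data frame `function_id`, `rmag_id`: which genomes encode
#'   which function.
#' @param abundance Matrix rMAG x sample of relative abundances.
#' @return Matrix function x sample of percentages.
#' @export
mw_score <- function(fun_map, abundance) {
  abundance <- as.matrix(abundance)
  fun_map <- unique(fun_map[, c("function_id", "rmag_id")])
  known <- fun_map$rmag_id %in% rownames(abundance)
  fun_map <- fun_map[known, , drop = FALSE]
  if (nrow(fun_map) == 0L) abort("no annotated genome appears in the abundance matrix")
  num <- rowsum(abundance[fun_map$rmag_id, , drop = FALSE],
                group = fun_map$function_id)
  denom <- colSums(num)
  if (any(denom == 0)) {
    warning("sample(s) with no annotated abundance reported as NA: ",
            paste(colnames(num)[denom == 0], collapse = ", "))
  }
  scores <- 100 * sweep(num, 2, denom, `/`)
  scores[, denom == 0] <- NA_real_
  scores
}

#' CAZyme summaries per pH group and per genome
#'
#' Counts distinct CAZy families per sample group (set union over the group's
#' genomes) and total CAZyme genes per rMAG.
#'
#' @param annotations Data frame `rmag_id`, `cazy_family` (`NA` for
#'   non-CAZyme genes).
#' @param rmag_groups Named character vector: rMAG id -> group label (e.g.
#'   pH class of its spring of origin).
#' @return List with `families_per_group` (data frame `group`, `n_families`)
#'   and `cazymes_per_rmag` (data frame `rmag_id`, `n_cazymes`).
#' @export
cazyme_summary <- function(annotations, rmag_groups) {
  caz <- annotations[!is.na(annotations$cazy_family) &
                       annotations$cazy_family != "", , drop = FALSE]
  per_rmag <- data.frame(rmag_id = names(rmag_groups),
                         n_cazymes = as.integer(
                           table(factor(caz$rmag_id, levels = names(rmag_groups)))),
                         stringsAsFactors = FALSE)
  caz$group <- rmag_groups[caz$rmag_id]
  groups <- sort(unique(unname(rmag_groups)))
  fams <- vapply(groups, function(g) {
    length(unique(caz$cazy_family[!is.na(caz$group) & caz$group == g]))
  }, integer(1))
  list(families_per_group = data.frame(group = groups, n_families = fams,
                                       stringsAsFactors = FALSE),
       cazymes_per_rmag = per_rmag)
}
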