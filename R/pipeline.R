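# End-to-end pipeline: detect repeat units in each protein, align them,
# infer a repeat-level tree, assign classes, build species profiles, and
# collapse to a putative species tree.

#' Run the repeat-domain phylogenetics pipeline
#'
#' Detection uses the two-stringency dot-matrix caller against a set of
#' curated reference domains (as in practice, where known repeat domains of
#' a well-annotated species anchor the search). The repeat-level tree is
#' neighbor joining on ML distances by default; classes come from k-medoids
#' on the tree's patristic distances; profiles (degenerate units excluded)
#' are collapsed into the parsimonious species tree.
#'
#' @param proteins a protein [sir_seqs], one entry per species (ids are the
#'   species names) or with `species` supplied.
#' @param reference_domains protein [sir_seqs]/character vector of reference
#'   repeat domains (each `domain_length` residues).
#' @param ers_anchor,prs_anchor optional anchor stubs; when given, linkers
#'   are extracted between them, otherwise whole proteins are scanned.
#' @param species optional named vector protein id -> species.
#' @param k number of repeat classes for k-medoids.
#' @param domain_length repeat-unit length.
#' @param high_fraction,low_fraction dot-matrix stringencies.
#' @param window,matrix_name dot-matrix parameters.
#' @param distance_model model name for ML distances (default DAYHOFF,
#'   uniform rates).
#' @param max_exact_terminals exact-search bound passed to the collapse.
#' @param include_degenerate count degenerate units in profiles.
#' @return list with `units`, `alignment`, `repeat_tree`, `classes`,
#'   `profiles`, `collapsed`.
#' @export
sir_pipeline <- function(proteins, reference_domains,
                         ers_anchor = NULL, prs_anchor = NULL,
                         species = NULL, k = 3, domain_length = 50,
                         high_fraction = 0.5, low_fraction = 0.3,
                         window = 11, matrix_name = "PAM250",
                         distance_model = "DAYHOFF",
                         max_exact_terminals = 6,
                         include_degenerate = FALSE) {
  if (is.null(species))
    species <- stats::setNames(proteins$id, proteins$id)
  all_units <- list()
  for (i in seq_len(nrow(proteins))) {
    prot <- proteins[i, , drop = FALSE]
    region <- if (!is.null(ers_anchor) && !is.null(prs_anchor)) {
      tryCatch(extract_linker(prot, ers_anchor, prs_anchor),
               error = function(e) NULL)
    } else {
      structure(list(protein_id = prot$id, start = 0L,
                     end = nchar(prot$residues),
                     sequence = prot$residues), class = "sir_linker")
    }
    if (is.null(region)) next
    units <- detect_degenerate_repeats(
      region, reference_domains,
      high_cfg = list(window = window, matrix_name = matrix_name,
                      min_score_fraction = high_fraction),
      low_cfg = list(window = window, matrix_name = matrix_name,
                     min_score_fraction = low_fraction),
      domain_length = domain_length,
      species = unname(species[prot$id]), protein_id = prot$id)
    if (nrow(units)) all_units[[length(all_units) + 1L]] <- units
  }
  units <- do.call(rbind, all_units)
  if (is.null(units) || nrow(units) < 3)
    sir_stop("pipeline found fewer than 3 repeat units")
  usable <- units[!units$degenerate | include_degenerate, , drop = FALSE]
  ids <- repeat_unit_ids(usable)
  aln <- progressive_msa(stats::setNames(usable$sequence, ids))
  model <- substitution_model(distance_model)
  dm <- ml_pairwise_distance(aln, model)
  repeat_tree <- neighbor_joining(dm)
  classes <- assign_repeat_classes(repeat_tree,
                                   k = min(k, length(ids)))
  profiles <- build_species_profiles(classes, units,
                                     species = sort(unique(unname(species))),
                                     include_degenerate = include_degenerate)
  collapsed <- collapse_to_species_tree(
    profiles, max_exact_terminals = max_exact_terminals)
  list(units = units, alignment = aln, repeat_tree = repeat_tree,
       classes = classes, profiles = profiles, collapsed = collapsed)
}
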