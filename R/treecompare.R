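# Bipartition extraction, Robinson-Foulds distance, and cross-algorithm
# branch-support annotation.

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge is encoded canonically as the sorted leaf set on the
#' side not containing the alphabetically smallest leaf, joined with commas.
#'
#' @param tree an [ape::phylo].
#' @return character vector of canonical split strings (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character(0))
  tree <- ape::unroot(tree)
  ref <- min(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (tp in seq_len(ntip)) below[[tp]] <- tree$tip.label[tp]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  out <- character(0)
  root <- ntip + 1L
  for (e in seq_len(nrow(post$edge))) {
    ch <- post$edge[e, 2]
    if (ch <= ntip || ch == root) next
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

edge_splits <- function(tree) {
  # canonical split string per internal node (NA for trivial edges)
  ntip <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (tp in seq_len(ntip)) below[[tp]] <- tree$tip.label[tp]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  res <- rep(NA_character_, ntip + tree$Nnode)   # indexed by child node
  inner <- if (tree$Nnode >= 2) (ntip + 2L):(ntip + tree$Nnode) else integer(0)
  for (node in inner) {
    side <- below[[node]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    res[node] <- paste(sort(side), collapse = ",")
  }
  # in a rooted tree both root children carry the same unrooted split;
  # keep a single labeled copy
  res[duplicated(res, incomparables = NA)] <- NA
  res
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets.
#' @param a,b [ape::phylo] trees on the identical leaf set.
#' @return nonnegative integer.
#' @export
robinson_foulds <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    sir_stop("leaf sets differ; only in first: {",
             paste(setdiff(a$tip.label, b$tip.label), collapse = ","),
             "}; only in second: {",
             paste(setdiff(b$tip.label, a$tip.label), collapse = ","), "}")
  sa <- tree_bipartitions(a)
  sb <- tree_bipartitions(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Annotate a tree with cross-algorithm branch support
#'
#' For each internal bipartition of the primary tree, counts in how many of
#' the three trees (the primary counts itself) the split occurs. Counts are
#' stored in `tree$support`, indexed by internal node number, and serialize
#' as `*` (2) or `**` (3) under [write_newick()]'s star scheme.
#'
#' @param primary the tree to annotate.
#' @param others list of exactly two further trees on the same leaf set.
#' @return `primary` with a `support` vector attached.
#' @export
annotate_consensus_support <- function(primary, others) {
  if (length(others) != 2) sir_stop("others must hold exactly 2 trees")
  for (o in others) {
    if (!setequal(primary$tip.label, o$tip.label))
      sir_stop("leaf sets differ; only in primary: {",
               paste(setdiff(primary$tip.label, o$tip.label), collapse = ","),
               "}; only in other: {",
               paste(setdiff(o$tip.label, primary$tip.label), collapse = ","),
               "}")
  }
  splits <- edge_splits(primary)
  sets <- lapply(others, tree_bipartitions)
  support <- rep(NA_real_, length(splits))
  for (node in seq_along(splits)) {
    if (is.na(splits[node])) next
    support[node] <- 1 + sum(vapply(sets, function(s) splits[node] %in% s,
                                    logical(1)))
  }
  primary$support <- support
  primary
}
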