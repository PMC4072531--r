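# Minimal unrooted-tree graph utilities: conversion to/from ape, canonical
# topology hashing, and SPR / NNI neighborhood generation used by the ML
# search and the Bayesian sampler.

graph_from_phylo <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  edges <- data.frame(a = tree$edge[, 1], b = tree$edge[, 2],
                      len = if (is.null(tree$edge.length))
                        rep(NA_real_, nrow(tree$edge))
                      else tree$edge.length)
  list(ntip = ntip, labels = tree$tip.label, edges = edges,
       next_id = max(edges$a, edges$b) + 1L)
}

graph_neighbors <- function(g) {
  nb <- list()
  add <- function(nb, x, y) {
    key <- as.character(x)
    nb[[key]] <- c(nb[[key]], y)
    nb
  }
  for (i in seq_len(nrow(g$edges))) {
    nb <- add(nb, g$edges$a[i], g$edges$b[i])
    nb <- add(nb, g$edges$b[i], g$edges$a[i])
  }
  nb
}

graph_to_newick <- function(g, with_lengths = TRUE) {
  nb <- list()
  len <- list()
  for (i in seq_len(nrow(g$edges))) {
    a <- as.character(g$edges$a[i]); b <- as.character(g$edges$b[i])
    nb[[a]] <- c(nb[[a]], g$edges$b[i]); nb[[b]] <- c(nb[[b]], g$edges$a[i])
    len[[paste(a, b)]] <- g$edges$len[i]; len[[paste(b, a)]] <- g$edges$len[i]
  }
  elen <- function(x, y) len[[paste(x, y)]]
  rec <- function(node, parent) {
    kids <- setdiff(nb[[as.character(node)]], parent)
    s <- if (!length(kids)) g$labels[node]
         else paste0("(", paste(vapply(kids, rec, character(1),
                                       parent = node), collapse = ","), ")")
    if (!is.null(parent) && with_lengths && !is.na(elen(node, parent)))
      s <- paste0(s, ":", sprintf("%.17g", elen(node, parent)))
    s
  }
  # root the serialization at an internal node adjacent to tip 1
  root <- nb[["1"]][1]
  kids <- nb[[as.character(root)]]
  paste0("(", paste(vapply(kids, rec, character(1), parent = root),
                    collapse = ","), ");")
}

graph_to_phylo <- function(g, with_lengths = TRUE) {
  ape::read.tree(text = graph_to_newick(g, with_lengths))
}

#' Canonical topology hash of an unrooted tree
#'
#' The sorted set of non-trivial bipartitions, each in canonical form;
#' identical strings iff identical unrooted topologies.
#' @param tree an [ape::phylo].
#' @return a single string.
#' @export
topology_hash <- function(tree) {
  paste(sort(tree_bipartitions(tree)), collapse = ";")
}

split_component <- function(g, drop_edge, start) {
  nb <- graph_neighbors(g)
  seen <- c(start)
  queue <- start
  a <- g$edges$a[drop_edge]; b <- g$edges$b[drop_edge]
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (y in nb[[as.character(x)]]) {
      if ((x == a && y == b) || (x == b && y == a)) next
      if (!(y %in% seen)) { seen <- c(seen, y); queue <- c(queue, y) }
    }
  }
  seen
}

suppress_degree2 <- function(edges, node) {
  inc <- which(edges$a == node | edges$b == node)
  if (length(inc) != 2) return(edges)
  other <- c(ifelse(edges$a[inc] == node, edges$b[inc], edges$a[inc]))
  newlen <- sum(edges$len[inc])
  edges <- edges[-inc, , drop = FALSE]
  rbind(edges, data.frame(a = other[1], b = other[2], len = newlen))
}

#' All SPR neighbors of an unrooted tree
#'
#' For every edge, each side of the induced bipartition is pruned in turn
#' and regrafted onto every edge of the remaining component; duplicate and
#' original topologies are removed. Branch lengths are carried through
#' (regraft edges are bisected; the pruned stalk keeps its length).
#'
#' @param tree an unrooted [ape::phylo] with >= 4 tips.
#' @return list of [ape::phylo] neighbors, deduplicated by topology.
#' @export
spr_neighbors <- function(tree) {
  g <- graph_from_phylo(tree)
  if (g$ntip < 4) return(list())
  seen <- topology_hash(tree)
  out <- list()
  E <- g$edges
  for (ei in seq_len(nrow(E))) {
    for (side in c("a", "b")) {
      v <- E[[side]][ei]                        # root of pruned subtree
      u <- E[[if (side == "a") "b" else "a"]][ei]
      comp_v <- split_component(g, ei, v)
      comp_u <- split_component(g, ei, u)
      if (length(comp_u) < 3) next              # nowhere new to regraft
      stalk_len <- E$len[ei]
      # remainder: drop the cut edge, suppress u if it became degree 2
      rem <- g$edges[-ei, , drop = FALSE]
      rem_nodes <- comp_u
      rem_edges <- rem[rem$a %in% rem_nodes & rem$b %in% rem_nodes, ,
                       drop = FALSE]
      sub_edges <- rem[rem$a %in% comp_v & rem$b %in% comp_v, , drop = FALSE]
      rem_edges <- suppress_degree2(rem_edges, u)
      for (ri in seq_len(nrow(rem_edges))) {
        x <- rem_edges$a[ri]; y <- rem_edges$b[ri]
        mid <- g$next_id
        half <- rem_edges$len[ri] / 2
        ne <- rbind(
          rem_edges[-ri, , drop = FALSE],
          data.frame(a = c(x, mid, mid), b = c(mid, y, v),
                     len = c(half, half, stalk_len)),
          sub_edges)
        g2 <- list(ntip = g$ntip, labels = g$labels, edges = ne,
                   next_id = mid + 1L)
        tr2 <- graph_to_phylo(g2)
        h <- topology_hash(tr2)
        if (!(h %in% seen)) {
          seen <- c(seen, h)
          out[[length(out) + 1L]] <- tr2
        }
      }
    }
  }
  out
}

#' One random NNI rearrangement
#'
#' Picks a random internal edge and swaps one subtree from each end;
#' branch lengths are preserved. Used as the topology proposal of the
#' Bayesian sampler.
#' @param tree unrooted [ape::phylo] with >= 4 tips.
#' @return a new [ape::phylo].
#' @export
random_nni <- function(tree) {
  g <- graph_from_phylo(tree)
  internal <- which(g$edges$a > g$ntip & g$edges$b > g$ntip)
  if (!length(internal)) return(tree)
  ei <- internal[sample.int(length(internal), 1)]
  u <- g$edges$a[ei]; v <- g$edges$b[ei]
  eu <- which((g$edges$a == u | g$edges$b == u) & seq_len(nrow(g$edges)) != ei)
  ev <- which((g$edges$a == v | g$edges$b == v) & seq_len(nrow(g$edges)) != ei)
  pick_u <- eu[sample.int(length(eu), 1)]
  pick_v <- ev[sample.int(length(ev), 1)]
  swap_end <- function(edges, idx, from, to) {
    if (edges$a[idx] == from) edges$a[idx] <- to else edges$b[idx] <- to
    edges
  }
  g$edges <- swap_end(g$edges, pick_u, u, v)
  g$edges <- swap_end(g$edges, pick_v, v, u)
  graph_to_phylo(g)
}
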