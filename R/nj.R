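# Saitou-Nei neighbor joining with documented tie-breaking and
# negative-branch handling.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken by
#' the lexicographically smallest label pair. Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch, so path
#' lengths between the joined taxa are preserved. The final three clusters
#' are resolved by the three-point formulas, leaving the usual unrooted
#' trifurcation.
#'
#' @param dm a `sir_distmat` (or a plain symmetric matrix with dimnames),
#'   >= 3 labels.
#' @return an unrooted [ape::phylo] tree; additive input matrices are
#'   recovered exactly (topology and branch lengths).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "sir_distmat")) {
    D <- dm$values; labels <- dm$labels
  } else {
    D <- as.matrix(dm); labels <- rownames(D)
  }
  n <- length(labels)
  if (n < 3) sir_stop("neighbor joining needs >= 3 labels")
  # each active cluster: newick fragment and its smallest member label
  frag <- labels
  key <- labels
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.17g", x)
  while (length(active) > 3) {
    k <- length(active)
    Dk <- D[active, active, drop = FALSE]
    r <- rowSums(Dk)
    Qm <- (k - 2) * Dk - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    ties <- which(Qm <= qmin + 1e-12, arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    pair_keys <- apply(ties, 1, function(ij) {
      pk <- sort(c(key[active[ij[1]]], key[active[ij[2]]]))
      paste(pk, collapse = "\r")
    })
    pick <- ties[order(pair_keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- D[i, j]
    bi <- 0.5 * dij + (r[pick[1]] - r[pick[2]]) / (2 * (k - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_frag <- paste0("(", frag[i], ":", fmt(bi), ",",
                       frag[j], ":", fmt(bj), ")")
    new_key <- min(key[i], key[j])
    others <- setdiff(active, c(i, j))
    dnew <- 0.5 * (D[i, others] + D[j, others] - dij)
    dnew <- pmax(dnew, 0)
    # reuse slot i for the merged cluster
    D[i, others] <- dnew; D[others, i] <- dnew; D[i, i] <- 0
    frag[i] <- new_frag; key[i] <- new_key
    active <- setdiff(active, j)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- 0.5 * (D[a, b] + D[a, c3] - D[b, c3])
  lb <- 0.5 * (D[a, b] + D[b, c3] - D[a, c3])
  lc <- 0.5 * (D[a, c3] + D[b, c3] - D[a, b])
  v <- c(la, lb, lc)
  for (x in 1:3) if (v[x] < 0) {
    others <- setdiff(1:3, x)
    v[others] <- v[others] + v[x] / 2
    v[x] <- 0
  }
  txt <- paste0("(", frag[a], ":", fmt(v[1]), ",", frag[b], ":", fmt(v[2]),
                ",", frag[c3], ":", fmt(v[3]), ");")
  ape::read.tree(text = txt)
}
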