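# Independent brute-force oracles used to freeze expected values.

# exhaustive global affine-gap alignment score by enumerating all monotone
# edit paths (small sequences only)
brute_align_score <- function(a, b, sub, gap_open, gap_extend) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, score + sub[ca[i], cb[j]], "m")
    if (i <= length(ca))
      rec(i + 1, j, score - (if (state == "u") gap_extend
                             else gap_open + gap_extend), "u")
    if (j <= length(cb))
      rec(i, j + 1, score - (if (state == "l") gap_extend
                             else gap_open + gap_extend), "l")
  }
  rec(1, 1, 0, "m")
  best
}

# exhaustive log-likelihood by summing over all internal-node state
# assignments, with transition matrices from Matrix::expm (independent of
# the package's spectral path)
brute_loglik <- function(tree, aln, model) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  m <- alignment_matrix(aln)[tree$tip.label, , drop = FALSE]
  idx <- matrix(match(m, AA20), nrow(m))
  Pmats <- list()
  for (r in seq_along(model$rates)) {
    Pmats[[r]] <- lapply(seq_len(nrow(tree$edge)), function(e)
      as.matrix(Matrix::expm(model$Q * tree$edge.length[e] *
                               model$rates[r])))
  }
  internals <- (ntip + 1):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  total <- 0
  for (col in seq_len(ncol(idx))) {
    like_site <- 0
    for (r in seq_along(model$rates)) {
      P <- Pmats[[r]]
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        st <- numeric(ntip + nnode)
        st[internals] <- grid[g, ]
        st[1:ntip] <- idx[, col]
        term <- unname(model$frequencies[grid[g, 1]])
        ok <- TRUE
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          if (ch <= ntip && is.na(st[ch])) next   # missing data: marginal 1
          pr <- P[[e]][st[par], st[ch]]
          term <- term * pr
          if (term == 0) { ok <- FALSE; break }
        }
        lik <- lik + term
      }
      like_site <- like_site + lik / length(model$rates)
    }
    total <- total + log(like_site)
  }
  total
}

# minimum Steiner tree cost by enumerating Hanan-grid Steiner subsets and
# taking the MST of each candidate node set (L1 metric)
brute_steiner_cost <- function(P) {
  keys <- apply(P, 1, paste, collapse = ",")
  vals <- lapply(seq_len(ncol(P)), function(ci) sort(unique(P[, ci])))
  G <- as.matrix(expand.grid(vals))
  gk <- apply(G, 1, paste, collapse = ",")
  term <- match(unique(keys), gk)
  D <- as.matrix(stats::dist(G, method = "manhattan"))
  mst_cost <- function(nodes) {
    if (length(nodes) < 2) return(0)
    Dm <- D[nodes, nodes]
    n <- length(nodes)
    intree <- 1; cost <- 0; dmin <- Dm[1, ]
    for (it in seq_len(n - 1)) {
      dmin[intree] <- Inf
      j <- which.min(dmin)
      cost <- cost + dmin[j]
      intree <- c(intree, j)
      dmin <- pmin(dmin, Dm[j, ])
    }
    cost
  }
  cand <- setdiff(seq_len(nrow(G)), term)
  best <- mst_cost(term)
  for (sz in seq_len(min(length(cand), max(length(term) - 2, 0)))) {
    for (comb in asplit(utils::combn(cand, sz), 2))
      best <- min(best, mst_cost(c(term, comb)))
  }
  unname(best)
}

# shortest path in the unit-step profile lattice by breadth-first search
bfs_edit_distance <- function(u, v, cap = 3) {
  key <- function(x) paste(x, collapse = ",")
  dist <- list(); dist[[key(u)]] <- 0
  q <- list(u)
  while (length(q)) {
    x <- q[[1]]; q <- q[-1]
    d <- dist[[key(x)]]
    if (key(x) == key(v)) return(d)
    for (i in seq_along(x)) for (s in c(-1, 1)) {
      y <- x; y[i] <- y[i] + s
      if (y[i] < 0 || y[i] > cap + 1) next
      if (is.null(dist[[key(y)]])) {
        dist[[key(y)]] <- d + 1
        q <- c(q, list(y))
      }
    }
  }
  stop("unreachable")
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ij <- sum_a * sum_b / n
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}
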