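# Shared fixtures: random sequences, model-based alignment simulation,
# planted-repeat linkers. Everything is generated in code under fixed seeds.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

rand_protein <- function(n, pool = AA20) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, n_subs) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(ch), n_subs)
  for (i in idx) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

# simulate an alignment down a tree under a sir_model (per-site gamma
# category fixed across the tree, as in the likelihood's mixture)
simulate_alignment <- function(tree, model, n_columns) {
  seqs <- list()
  rates <- model$rates[sample(length(model$rates), n_columns, replace = TRUE)]
  rec <- function(node, s) {
    kids <- which(tree$edge[, 1] == node)
    if (!length(kids)) {
      seqs[[tree$tip.label[node]]] <<- s
      return(invisible())
    }
    for (e in kids) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      news <- vapply(seq_along(ch), function(i) {
        P <- prob_matrix(model, tree$edge.length[e], rates[i])
        sample(AA20, 1, prob = P[ch[i], ])
      }, character(1))
      rec(tree$edge[e, 2], paste(news, collapse = ""))
    }
  }
  rec(length(tree$tip.label) + 1L, stationary_sequence(model, n_columns))
  sir_alignment(names(seqs), unlist(seqs))
}

# random unrooted tree with branch lengths
rand_tree <- function(ntip, min_len = 0.05, max_len = 0.8) {
  tr <- ape::unroot(ape::rtree(ntip))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr$tip.label <- paste0("t", seq_len(ntip))
  tr
}

# planted-repeat linker: spacers (biased composition) around planted copies
planted_linker <- function(domain, starts, identity = 1, total_len = NULL) {
  dl <- nchar(domain)
  if (is.null(total_len)) total_len <- max(starts) + dl + 20
  spacer_pool <- c("G", "P", "Q", "E", "S", "T")
  ch <- strsplit(rand_protein(total_len, spacer_pool), "", fixed = TRUE)[[1]]
  for (s in starts) {
    copy <- if (identity >= 1) domain
            else mutate_protein(domain, round((1 - identity) * dl))
    ch[(s + 1):(s + dl)] <- strsplit(copy, "", fixed = TRUE)[[1]]
  }
  paste(ch, collapse = "")
}
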