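# Minimal Bayesian MCMC over tree space: Metropolis-Hastings with NNI
# topology proposals, branch-length multiplier proposals and a sliding
# window on the gamma shape; majority-rule consensus with bipartition
# posteriors after discarding a burn-in fraction of the samples.

#' Bayesian tree sampling by Metropolis-Hastings
#'
#' Priors: exponential(10) on branch lengths, uniform on topologies, uniform
#' on the gamma shape within its bounds. Proposals: random NNI (when > 3
#' taxa), branch-length multiplier, and, for gamma models, a sliding window
#' on alpha. The consensus is the majority-rule topology of the post-burn-in
#' samples with bipartition posterior probabilities attached (in
#' `$support`, so [write_newick()] can emit them as numeric labels).
#'
#' @param aln a `sir_alignment`.
#' @param model a `sir_model` (its alpha is the starting value when gamma
#'   rates are used).
#' @param generations number of MCMC generations (>= 1000).
#' @param sample_every sampling interval.
#' @param burnin_fraction fraction of samples discarded (default 0.25).
#' @param seed RNG seed; runs are reproducible given the seed.
#' @param start_tree optional starting tree.
#' @return list with `consensus` (phylo + `support` posteriors),
#'   `split_posteriors`, `trace` (data frame: generation, logLik,
#'   tree_length, alpha), `acceptance_rate`, `n_samples`, `n_retained`.
#' @export
bayesian_mcmc <- function(aln, model, generations = 10000,
                          sample_every = 10, burnin_fraction = 0.25,
                          seed = 1, start_tree = NULL) {
  if (generations < 1000) sir_stop("generations must be >= 1000")
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    sir_stop("burnin_fraction must be in [0, 1)")
  set.seed(seed)
  pat <- aln_patterns(aln)
  lnl_of <- function(tree, mod) {
    sum(pat$weights * log(pmax(site_likelihoods(tree, pat, mod), 1e-300)))
  }
  tree <- if (is.null(start_tree)) nj_start_tree(aln, model) else start_tree
  check_labels(tree, aln$ids)
  has_gamma <- !is.null(model$alpha)
  alpha <- if (has_gamma) model$alpha else NULL
  mod <- model
  log_prior <- function(tr) sum(stats::dexp(tr$edge.length, rate = 10,
                                            log = TRUE))
  cur_lnl <- lnl_of(tree, mod)
  cur_post <- cur_lnl + log_prior(tree)
  n_accept <- 0L
  samples <- list()
  trace <- list()
  can_nni <- length(aln$ids) > 3
  for (gen in seq_len(generations)) {
    move <- sample(c("topology", "blen", "alpha"), 1,
                   prob = c(if (can_nni) 0.4 else 0, 0.5,
                            if (has_gamma) 0.1 else 0))
    prop <- tree; prop_mod <- mod; prop_alpha <- alpha; log_hastings <- 0
    if (move == "topology") {
      prop <- random_nni(tree)
    } else if (move == "blen") {
      e <- sample.int(nrow(tree$edge), 1)
      mult <- exp(1.0 * (stats::runif(1) - 0.5))
      prop$edge.length[e] <- tree$edge.length[e] * mult
      log_hastings <- log(mult)
    } else {
      prop_alpha <- alpha + stats::runif(1, -0.3, 0.3)
      while (prop_alpha < 0.05 || prop_alpha > 50) {  # reflect at bounds
        if (prop_alpha < 0.05) prop_alpha <- 0.1 - prop_alpha
        if (prop_alpha > 50) prop_alpha <- 100 - prop_alpha
      }
      prop_mod <- substitution_model(mod$name, alpha = prop_alpha, n_categories = mod$k)
    }
    prop_lnl <- lnl_of(prop, prop_mod)
    prop_post <- prop_lnl + log_prior(prop)
    if (log(stats::runif(1)) < prop_post - cur_post + log_hastings) {
      tree <- prop; mod <- prop_mod; alpha <- prop_alpha
      cur_lnl <- prop_lnl; cur_post <- prop_post
      n_accept <- n_accept + 1L
    }
    if (gen %% sample_every == 0) {
      samples[[length(samples) + 1L]] <- tree
      trace[[length(trace) + 1L]] <-
        data.frame(generation = gen, logLik = cur_lnl,
                   tree_length = sum(tree$edge.length),
                   alpha = if (has_gamma) alpha else NA_real_)
    }
  }
  n_samples <- length(samples)
  n_burn <- floor(burnin_fraction * n_samples)
  retained <- samples[(n_burn + 1):n_samples]
  split_counts <- table(unlist(lapply(retained, tree_bipartitions)))
  post <- as.numeric(split_counts) / length(retained)
  names(post) <- names(split_counts)
  cons <- consensus_from_samples(retained, post)
  list(consensus = cons, split_posteriors = post,
       trace = do.call(rbind, trace),
       acceptance_rate = n_accept / generations,
       n_samples = n_samples, n_retained = length(retained))
}

consensus_from_samples <- function(trees, post) {
  if (length(unique(vapply(trees, topology_hash, character(1)))) == 1) {
    cons <- trees[[1]]
    cons$edge.length <- NULL
  } else {
    class(trees) <- "multiPhylo"
    cons <- ape::consensus(trees, p = 0.5)
  }
  splits <- edge_splits(cons)
  support <- rep(NA_real_, length(splits))
  for (node in seq_along(splits)) {
    if (is.na(splits[node])) next
    support[node] <- if (splits[node] %in% names(post))
      post[[splits[node]]] else NA_real_
  }
  cons$support <- support
  cons
}
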