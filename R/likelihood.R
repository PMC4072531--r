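# Felsenstein pruning log-likelihood with discrete-gamma mixture, and
# coordinate-wise branch-length optimization.

aln_patterns <- function(aln) {
  m <- alignment_matrix(aln)
  idx <- matrix(match(m, AA_STATES), nrow(m))   # NA = gap/ambiguous = missing
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  states <- idx[, u, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[u])))
  npat <- sum(u)
  tipmat <- vector("list", nrow(states))
  for (tp in seq_len(nrow(states))) {
    Pm <- matrix(0, 20, npat)
    st <- states[tp, ]
    known <- !is.na(st)
    Pm[, !known] <- 1
    Pm[cbind(st[known], which(known))] <- 1
    tipmat[[tp]] <- Pm
  }
  list(states = states, weights = w, ids = aln$ids, tipmat = tipmat,
       n_columns = ncol(m))
}

check_labels <- function(tree, ids) {
  miss_t <- setdiff(ids, tree$tip.label)
  miss_a <- setdiff(tree$tip.label, ids)
  if (length(miss_t) || length(miss_a))
    sir_stop("leaf/row label mismatch; only in alignment: {",
             paste(miss_t, collapse = ","), "}; only in tree: {",
             paste(miss_a, collapse = ","), "}")
}

site_likelihoods <- function(tree, pat, model) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- ncol(pat$states)
  ord <- ape::reorder.phylo(tree, "postorder")
  edge <- ord$edge
  elen <- ord$edge.length
  tip_row <- match(tree$tip.label, pat$ids)
  nrates <- length(model$rates)
  sitelik <- numeric(npat)
  evec <- model$evec; ivec <- model$ivec; eval <- model$eval
  root <- edge[nrow(edge), 1]
  for (r in seq_len(nrates)) {
    rate <- model$rates[r]
    partial <- vector("list", nnode)
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1]; ch <- edge[e, 2]
      P <- evec %*% (exp(eval * (elen[e] * rate)) * ivec)
      child <- if (ch <= ntip) pat$tipmat[[tip_row[ch]]] else partial[[ch]]
      contrib <- P %*% child
      contrib[contrib < 0] <- 0
      partial[[par]] <- if (is.null(partial[[par]])) contrib
                        else partial[[par]] * contrib
    }
    sitelik <- sitelik + drop(model$frequencies %*% partial[[root]]) / nrates
  }
  sitelik
}

pat_loglik <- function(tree, pat, model) {
  sum(pat$weights * log(pmax(site_likelihoods(tree, pat, model), 1e-300)))
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under a reversible amino-acid model, sites
#' independent, with the discrete-gamma category mixture averaged at equal
#' weights. Gaps (and `X`/`*`) are treated as missing data (partial
#' likelihood 1 over all states).
#'
#' @param tree [ape::phylo] with branch lengths; leaf labels must equal the
#'   alignment row ids.
#' @param aln a `sir_alignment`.
#' @param model a `sir_model`.
#' @return the log-likelihood (natural log).
#' @export
log_likelihood <- function(tree, aln, model) {
  if (is.null(tree$edge.length)) sir_stop("tree has no branch lengths")
  check_labels(tree, aln$ids)
  pat_loglik(tree, aln_patterns(aln), model)
}

optimize_bl_pat <- function(tree, pat, model, lower = 1e-9, upper = 10,
                            tol = 1e-4, max_cycles = 4, init = 0.1,
                            brent_tol = 1e-6) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(init, nrow(tree$edge))
  cur <- pat_loglik(tree, pat, model)
  for (cycle in seq_len(max_cycles)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        pat_loglik(tree, pat, model)
      }
      opt <- stats::optimize(f, c(lower, upper), maximum = TRUE,
                             tol = brent_tol)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) break
  }
  list(tree = tree, logLik = cur)
}

#' Optimize branch lengths by coordinate-wise Brent search
#'
#' Cycles over branches, maximizing the log-likelihood one branch at a time
#' by bounded one-dimensional search (tolerance 1e-6), until a full cycle
#' improves the log-likelihood by less than `tol` or `max_cycles` is
#' reached.
#'
#' @param tree [ape::phylo]; missing branch lengths start at `init`.
#' @param aln,model as in [log_likelihood()].
#' @param lower,upper branch-length bounds.
#' @param tol convergence tolerance on the log-likelihood per cycle.
#' @param max_cycles maximum number of full cycles.
#' @param init initial value for missing branch lengths.
#' @return list with the re-lengthed `tree` and its `logLik`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, lower = 1e-9,
                                    upper = 10, tol = 1e-4, max_cycles = 4,
                                    init = 0.1) {
  check_labels(tree, aln$ids)
  optimize_bl_pat(tree, aln_patterns(aln), model, lower, upper, tol,
                  max_cycles, init)
}
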