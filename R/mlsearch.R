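# Maximum-likelihood tree search: NJ starting tree on ML distances, SPR
# hill-climbing with screen-and-refine neighbor evaluation, and BIC-based
# model selection.

nj_start_tree <- function(aln, model) {
  uni <- substitution_model(model$name)         # uniform-rate distances
  dm <- ml_pairwise_distance(aln, uni)
  tr <- neighbor_joining(dm)
  tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
  tr
}

#' Maximum-likelihood tree search by SPR hill climbing
#'
#' Starts from neighbor joining on ML distances (or a supplied tree),
#' optimizes branch lengths, then repeatedly scores the full SPR
#' neighborhood. Neighbors are screened with branch lengths carried over
#' from the current tree (one quick optimization cycle), the best few are
#' refined with full branch-length optimization, and the search accepts the
#' best refined neighbor while it improves the log-likelihood by more than
#' `improve_tol`. The final log-likelihood is never below the starting one.
#'
#' @param aln a `sir_alignment` with >= 3 rows (>= 4 for an actual search;
#'   3 rows have a unique unrooted topology).
#' @param model a `sir_model`.
#' @param start_tree optional starting [ape::phylo].
#' @param improve_tol minimal log-likelihood gain to accept an SPR move.
#' @param refine_top number of screened neighbors refined per iteration.
#' @param max_iter safety cap on accepted moves.
#' @return list with `tree` (optimized branch lengths), `logLik`,
#'   `start_logLik` and `n_moves`.
#' @export
ml_search <- function(aln, model, start_tree = NULL, improve_tol = 1e-4,
                      refine_top = 3, max_iter = 50) {
  n <- length(aln$ids)
  if (n < 3) sir_stop("need >= 3 sequences")
  m <- alignment_matrix(aln)
  if (any(apply(m, 1, function(r) all(r == "-"))))
    sir_stop("alignment contains an all-gap row")
  tree <- if (is.null(start_tree)) nj_start_tree(aln, model)
          else start_tree
  check_labels(tree, aln$ids)
  pat <- aln_patterns(aln)
  fit <- optimize_bl_pat(tree, pat, model)
  start_lnl <- fit$logLik
  if (n == 3)
    return(list(tree = fit$tree, logLik = fit$logLik,
                start_logLik = start_lnl, n_moves = 0L))
  n_moves <- 0L
  repeat {
    if (n_moves >= max_iter) break
    nbs <- spr_neighbors(fit$tree)
    if (!length(nbs)) break
    screen <- vapply(nbs, function(tr) {
      optimize_bl_pat(tr, pat, model, max_cycles = 1, brent_tol = 1e-4)$logLik
    }, numeric(1))
    cand <- order(screen, decreasing = TRUE)[seq_len(min(refine_top,
                                                         length(nbs)))]
    best <- NULL
    for (ci in cand) {
      ref <- optimize_bl_pat(nbs[[ci]], pat, model)
      if (is.null(best) || ref$logLik > best$logLik) best <- ref
    }
    if (best$logLik > fit$logLik + improve_tol) {
      fit <- best
      n_moves <- n_moves + 1L
    } else break
  }
  list(tree = fit$tree, logLik = fit$logLik, start_logLik = start_lnl,
       n_moves = n_moves)
}

#' Select the best-fitting substitution model by BIC
#'
#' Each candidate is scored on its own NJ starting topology with branch
#' lengths (and the gamma shape, where present) optimized;
#' BIC = -2 lnL + p log(n_columns) with p = number of branches, plus one for
#' a free gamma shape. Ties go to the candidate with fewer parameters.
#'
#' @param aln a `sir_alignment`.
#' @param candidates list of specs, each a list with `name` and optional
#'   `alpha` (`NA` means "estimate"); default crosses Dayhoff/WAG with
#'   uniform rates and Gamma(4).
#' @return list with `best` (a `sir_model`), `best_tree`, and `table`
#'   (name, gamma, lnL, p, BIC).
#' @export
select_model <- function(aln, candidates = NULL) {
  if (is.null(candidates))
    candidates <- list(list(name = "DAYHOFF", alpha = NULL),
                       list(name = "WAG", alpha = NULL),
                       list(name = "DAYHOFF", alpha = NA),
                       list(name = "WAG", alpha = NA))
  if (!length(candidates)) sir_stop("empty candidate list")
  ncol_aln <- alignment_ncol(aln)
  rows <- list()
  fits <- list()
  for (ci in seq_along(candidates)) {
    spec <- candidates[[ci]]
    est_alpha <- !is.null(spec$alpha) && is.na(spec$alpha)
    model <- if (is.null(spec$alpha)) substitution_model(spec$name)
             else substitution_model(spec$name,
                                     alpha = if (est_alpha) 1 else spec$alpha)
    tree <- nj_start_tree(aln, model)
    fit <- optimize_branch_lengths(tree, aln, model)
    if (est_alpha) {
      for (round in 1:2) {
        af <- function(a) {
          m2 <- substitution_model(spec$name, alpha = a)
          log_likelihood(fit$tree, aln, m2)
        }
        opt <- stats::optimize(af, c(0.05, 50), maximum = TRUE, tol = 1e-4)
        model <- substitution_model(spec$name, alpha = opt$maximum)
        fit <- optimize_branch_lengths(fit$tree, aln, model)
      }
    }
    p <- nrow(fit$tree$edge) + as.integer(!is.null(model$alpha))
    rows[[ci]] <- data.frame(name = model$name,
                             gamma = !is.null(model$alpha),
                             alpha = if (is.null(model$alpha)) NA_real_
                                     else model$alpha,
                             logLik = fit$logLik, p = p,
                             BIC = -2 * fit$logLik + p * log(ncol_aln))
    fits[[ci]] <- list(model = model, fit = fit)
  }
  tab <- do.call(rbind, rows)
  best_i <- order(round(tab$BIC, 8), tab$p)[1]
  list(best = fits[[best_i]]$model, best_tree = fits[[best_i]]$fit$tree,
       table = tab)
}
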