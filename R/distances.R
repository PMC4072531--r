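# Maximum-likelihood pairwise distances under an empirical model with
# uniform rates (the neighbor-joining input).

#' Construct a distance matrix object
#' @param labels taxon labels.
#' @param values symmetric nonnegative matrix with zero diagonal.
#' @param saturated optional logical matrix flagging capped entries.
#' @return a `sir_distmat`.
#' @export
distance_matrix <- function(labels, values, saturated = NULL) {
  values <- as.matrix(values)
  dimnames(values) <- list(labels, labels)
  if (any(abs(values - t(values)) > 1e-9))
    sir_stop("distance matrix not symmetric")
  if (any(diag(values) != 0)) sir_stop("nonzero diagonal")
  if (any(values < 0)) sir_stop("negative distances")
  if (any(!is.finite(values))) sir_stop("non-finite distances")
  if (is.null(saturated))
    saturated <- matrix(FALSE, nrow(values), ncol(values))
  dimnames(saturated) <- dimnames(values)
  structure(list(labels = labels, values = values, saturated = saturated),
            class = "sir_distmat")
}

#' Maximum-likelihood pairwise distances
#'
#' For each pair of rows, the distance is the time t maximizing
#' sum over shared-residue sites of log(pi_a P_ab(t)) under the model with
#' uniform rates, optimized on \[1e-8, d_max\]. Columns with a gap in either
#' row are skipped pairwise; entries reaching `d_max` are flagged saturated.
#'
#' @param aln a `sir_alignment` with >= 2 rows.
#' @param model a `sir_model` (its gamma structure, if any, is ignored:
#'   distances assume uniform rates).
#' @param d_max saturation cap (default 10).
#' @return a `sir_distmat`.
#' @export
ml_pairwise_distance <- function(aln, model, d_max = 10) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2) sir_stop("need >= 2 rows")
  idx <- matrix(match(m, AA_STATES), n)       # NA for gaps / ambiguity
  D <- matrix(0, n, n)
  Sat <- matrix(FALSE, n, n)
  logpi <- log(model$frequencies)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    if (!any(ok))
      sir_stop("no shared residue columns between '", aln$ids[i],
               "' and '", aln$ids[j], "'")
    N <- matrix(0, 20, 20)
    tab <- table(factor(idx[i, ok], levels = 1:20),
                 factor(idx[j, ok], levels = 1:20))
    N[] <- as.numeric(tab)
    obj <- function(t) {
      P <- prob_matrix(model, t)
      sum(N * log(pmax(model$frequencies * P, 1e-300)))
    }
    opt <- stats::optimize(obj, c(1e-8, d_max), maximum = TRUE,
                           tol = 1e-10)
    cand_t <- c(1e-8, opt$maximum, d_max)
    cand_v <- c(obj(1e-8), opt$objective, obj(d_max))
    best <- which.max(cand_v)
    d <- cand_t[best]
    if (best == 3 || d >= d_max - 1e-6) { d <- d_max; Sat[i, j] <- Sat[j, i] <- TRUE }
    if (best == 1) d <- 0
    D[i, j] <- D[j, i] <- d
  }
  distance_matrix(aln$ids, D, Sat)
}
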