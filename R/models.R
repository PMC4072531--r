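# Empirical amino-acid substitution models (Dayhoff, WAG), discrete gamma
# rate categories, and transition probabilities.

AA_STATES <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
               "F","P","S","T","W","Y","V")

fetch_aa_model <- function(name) {
  f <- utils::getFromNamespace("getModelAA", "phangorn")
  Q <- NULL; bf <- NULL
  f(name, bf = TRUE, Q = TRUE)
  list(Q = Q, bf = bf)
}

#' Construct an amino-acid substitution model
#'
#' Builds the reversible rate matrix Q from published exchangeabilities and
#' stationary frequencies (Dayhoff 1978 or Whelan & Goldman 2001 tables),
#' normalized to one expected substitution per site per unit time
#' (-sum pi_i Q_ii = 1). Among-site rate variation is modeled by k
#' equal-probability discrete gamma categories when `alpha` is given;
#' `alpha = NULL` means uniform rates.
#'
#' @param name `"WAG"` or `"DAYHOFF"`.
#' @param alpha gamma shape (NULL = uniform rates).
#' @param n_categories number of gamma categories (default 4).
#' @return a `sir_model`: list with `name`, `exchangeabilities` (symmetric
#'   20x20), `frequencies`, normalized `Q`, spectral decomposition for fast
#'   P(t), `alpha`, `k` and the category `rates`.
#' @export
substitution_model <- function(name = c("WAG", "DAYHOFF"), alpha = NULL,
                               n_categories = 4L) {
  name <- match.arg(toupper(name), c("WAG", "DAYHOFF"))
  if (!is.null(alpha) && alpha <= 0) sir_stop("alpha must be positive")
  if (n_categories < 1) sir_stop("n_categories must be >= 1")
  tab <- fetch_aa_model(if (name == "DAYHOFF") "Dayhoff" else "WAG")
  R <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  R[lower.tri(R)] <- tab$Q
  R <- R + t(R)
  pi <- tab$bf
  names(pi) <- AA_STATES
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(AA_STATES, AA_STATES)
  # reversible Q is similar to a symmetric matrix: D^{1/2} Q D^{-1/2}
  sp <- sqrt(pi)
  Sy <- diag(sp) %*% Q %*% diag(1 / sp)
  eg <- eigen((Sy + t(Sy)) / 2, symmetric = TRUE)
  rates <- if (is.null(alpha)) 1 else discrete_gamma_rates(alpha, n_categories)
  structure(list(name = name, exchangeabilities = R, frequencies = pi,
                 Q = Q,
                 evec = diag(1 / sp) %*% eg$vectors,
                 ivec = t(eg$vectors) %*% diag(sp),
                 eval = eg$values,
                 alpha = alpha,
                 k = if (is.null(alpha)) 1L else as.integer(n_categories),
                 rates = rates),
            class = "sir_model")
}

#' @export
print.sir_model <- function(x, ...) {
  cat(sprintf("Substitution model %s%s\n", x$name,
              if (is.null(x$alpha)) " (uniform rates)"
              else sprintf(" + Gamma(alpha=%.4g, k=%d)", x$alpha, x$k)))
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model a `sir_model`.
#' @param t branch length (expected substitutions per site at rate 1).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 20x20 stochastic matrix.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  P <- model$evec %*% (exp(model$eval * t * rate) * model$ivec)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_STATES, AA_STATES)
  P
}

#' Equal-probability discrete gamma rate categories
#'
#' Category rates are the means of the k equal-probability slices of
#' Gamma(alpha, alpha) (mean 1), so the average category rate is exactly 1.
#'
#' @param alpha gamma shape, > 0.
#' @param k number of categories, >= 1.
#' @return numeric vector of k rates.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0) sir_stop("alpha must be positive")
  k <- as.integer(k)
  if (k < 1) sir_stop("k must be >= 1")
  if (k == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X ; X <= b] for Gamma(a, a) is pgamma(b, a + 1, a): mean of each slice
  cum <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(cum)
}

#' Draw a random protein sequence from a model's stationary frequencies
#' @param model a `sir_model`.
#' @param length sequence length.
#' @return a protein string.
#' @export
stationary_sequence <- function(model, length) {
  paste(sample(AA_STATES, length, replace = TRUE, prob = model$frequencies),
        collapse = "")
}

#' Evolve a protein string for a given expected distance
#'
#' Each site independently transitions according to P(distance); the exact
#' finite-time law of the substitution process, used by the simulator.
#' @param model a `sir_model`.
#' @param seq protein string (model states only).
#' @param distance expected substitutions per site.
#' @return the evolved string.
#' @export
evolve_string <- function(model, seq, distance) {
  if (distance <= 0) return(seq)
  P <- prob_matrix(model, distance)
  ch <- seq_chars(seq)
  idx <- match(ch, AA_STATES)
  new_idx <- vapply(idx, function(i) {
    sample.int(20L, 1L, prob = P[i, ])
  }, integer(1))
  paste(AA_STATES[new_idx], collapse = "")
}
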