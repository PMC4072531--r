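#' Parse a Newick string or file
#'
#' Thin validator over [ape::read.tree()]. Missing branch lengths are left
#' absent (no `edge.length` element), never coerced to zero. Unbalanced
#' parentheses are reported with their character position.
#'
#' @param text Newick text (used when `file` is `NULL`).
#' @param file optional path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) sir_stop("parse_newick: give text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  prev <- ""
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        sir_stop("Newick parse error at position ", i, ": unbalanced ')'")
      if (prev == ",")
        sir_stop("Newick parse error at position ", i, ": dangling comma")
    }
    if (ch == "," && prev %in% c("(", ","))
      sir_stop("Newick parse error at position ", i, ": dangling comma")
    if (!grepl("\\s", ch)) prev <- ch
  }
  if (depth != 0L)
    sir_stop("Newick parse error: ", depth, " unclosed '('")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) sir_stop("Newick parse error: ", text)
  tr
}

format_brlen <- function(x, digits = 6) sprintf(paste0("%.", digits, "f"), x)

#' Serialize a tree to Newick
#'
#' Branch lengths are written to six decimals. Internal-edge support can be
#' written as node labels under two schemes: `"stars"` renders an
#' algorithm-agreement count of 2 as `*` and 3 as `**` (counts of 1 get no
#' label); `"numeric"` writes the support value (e.g. a posterior) as-is.
#' Supports are read from `tree$support`, a vector indexed by internal node
#' number (`Ntip+1 ..`), as attached by [annotate_consensus_support()] or
#' [bayesian_mcmc()].
#'
#' @param tree an [ape::phylo] tree.
#' @param file optional path; when given the text is also written there.
#' @param support `"none"`, `"stars"` or `"numeric"`.
#' @param digits decimals for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL,
                         support = c("none", "stars", "numeric"), digits = 6) {
  support <- match.arg(support)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  sup <- tree$support
  lab_for <- function(node) {
    if (support == "none" || is.null(sup)) return("")
    v <- if (node <= length(sup)) sup[node] else NA_real_
    if (is.na(v)) return("")
    if (support == "stars") {
      if (v >= 3) return("**")
      if (v >= 2) return("*")
      return("")
    }
    format(v)
  }
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- tree$tip.label[node]
    } else {
      rows <- kids[[as.character(node)]]
      parts <- vapply(rows, function(r) rec(tree$edge[r, 2], r), character(1))
      s <- paste0("(", paste(parts, collapse = ","), ")", lab_for(node))
    }
    if (!is.null(edge_idx) && has_len)
      s <- paste0(s, ":", format_brlen(tree$edge.length[edge_idx], digits))
    s
  }
  out <- paste0(rec(root, NULL), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
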