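# Global pairwise alignment (affine-gap Needleman-Wunsch with fixed
# tie-breaking) and percent identity.

#' Construct an alignment object
#'
#' @param ids row identifiers.
#' @param rows equal-length gapped strings (gap = `-`).
#' @param validate check equal lengths, no all-gap column, and row/gap
#'   consistency.
#' @return a `sir_alignment`.
#' @export
sir_alignment <- function(ids, rows, validate = TRUE) {
  x <- structure(list(ids = as.character(ids), rows = as.character(rows)),
                 class = "sir_alignment")
  if (validate) {
    if (length(unique(nchar(x$rows))) != 1)
      sir_stop("alignment rows have unequal lengths")
    m <- alignment_matrix(x)
    if (ncol(m) > 0 && any(colSums(m != "-") == 0))
      sir_stop("alignment contains an all-gap column")
  }
  x
}

#' @export
print.sir_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d rows x %d columns\n",
              length(x$rows), if (length(x$rows)) nchar(x$rows[1]) else 0L))
  invisible(x)
}

#' Alignment as a character matrix (rows x columns)
#' @param aln a `sir_alignment`.
#' @return character matrix with row names `aln$ids`.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), 0, 0)
  rownames(m) <- aln$ids
  m
}

#' Remove gaps from an alignment row
#' @param aln a `sir_alignment`.
#' @param i row index.
#' @return the ungapped source sequence.
#' @export
alignment_degap <- function(aln, i) gsub("-", "", aln$rows[i], fixed = TRUE)

#' Number of alignment columns
#' @param aln a `sir_alignment`.
#' @return integer column count.
#' @export
alignment_ncol <- function(aln) if (length(aln$rows)) nchar(aln$rows[1]) else 0L

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment; a gap of length L costs
#' `gap_open + L * gap_extend`. Traceback ties are resolved deterministically
#' (diagonal, then up, then left), so identical inputs always give identical
#' alignments.
#'
#' @param a,b single-row protein [sir_seqs] or plain nonempty strings.
#' @param matrix_name scoring matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list with `alignment` (2-row `sir_alignment`) and `score`.
#' @export
global_pairwise_align <- function(a, b, matrix_name = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.5) {
  sa <- if (is.data.frame(a)) a$residues[1] else as.character(a)
  sb <- if (is.data.frame(b)) b$residues[1] else as.character(b)
  ida <- if (is.data.frame(a)) a$id[1] else "a"
  idb <- if (is.data.frame(b)) b$id[1] else "b"
  if (!nzchar(sa) || !nzchar(sb)) sir_stop("empty input sequence")
  sub <- score_matrix(matrix_name)
  ca <- seq_chars(sa); cb <- seq_chars(sb)
  if (any(!ca %in% rownames(sub)) || any(!cb %in% rownames(sub)))
    sir_stop("sequence contains residues absent from ", matrix_name)
  S <- matrix(as.numeric(sub[ca, cb]), nrow = length(ca))
  res <- .gotoh_align(S, gap_open, gap_extend)
  path <- res$path
  row_a <- ifelse(path[, 1] > 0, ca[pmax(path[, 1], 1)], "-")
  row_b <- ifelse(path[, 2] > 0, cb[pmax(path[, 2], 1)], "-")
  list(alignment = sir_alignment(c(ida, idb),
                                 c(paste(row_a, collapse = ""),
                                   paste(row_b, collapse = ""))),
       score = res$score)
}

#' Percent identity of a two-row alignment
#'
#' 100 x (columns with identical residues) / (counted columns). Gap-gap
#' columns are never counted. Under `exclude_terminal_gaps` (the default),
#' columns lying within a leading or trailing gap of either row are also
#' removed from the denominator.
#'
#' @param aln a 2-row `sir_alignment`.
#' @param mode `"exclude_terminal_gaps"` or `"all_columns"`.
#' @return percentage in \[0, 100\].
#' @export
percent_identity <- function(aln,
                             mode = c("exclude_terminal_gaps", "all_columns")) {
  mode <- match.arg(mode)
  if (length(aln$rows) != 2)
    sir_stop("percent_identity requires exactly 2 rows, got ",
             length(aln$rows))
  m <- alignment_matrix(aln)
  keep <- !(m[1, ] == "-" & m[2, ] == "-")
  if (mode == "exclude_terminal_gaps") {
    core <- function(r) {
      ng <- which(r != "-")
      seq_along(r) >= min(ng) & seq_along(r) <= max(ng)
    }
    keep <- keep & core(m[1, ]) & core(m[2, ])
  }
  n <- sum(keep)
  if (n == 0) sir_stop("no countable columns")
  ident <- sum(m[1, keep] == m[2, keep] & m[1, keep] != "-")
  100 * ident / n
}
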