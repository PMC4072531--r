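# Windowed (Pustell-style) dot-matrix comparison of two protein sequences.

#' Compute a windowed dot matrix between two protein sequences
#'
#' Slides an ungapped window of odd length along both sequences and marks the
#' coordinate pair of the window centers whenever the summed substitution
#' score reaches `min_score_fraction` of the maximum attainable score for
#' that pair of windows (the smaller of the two windows' perfect self-match
#' scores). Diagonal runs of marks indicate conserved segments; off-diagonal
#' runs indicate repeats.
#'
#' @param query,reference single-row protein [sir_seqs] or plain strings.
#' @param window odd window length in residues (`3 <= window <= min length`).
#' @param matrix_name scoring matrix, see [score_matrix()].
#' @param min_score_fraction threshold in (0, 1] as a fraction of the
#'   maximum attainable window score.
#' @return a `sir_dotmatrix`: list with `marks` (two-column 0-based matrix of
#'   query/reference window centers), the window-score matrix over valid
#'   centers, and the call parameters.
#' @export
compute_dot_matrix <- function(query, reference, window = 11,
                               matrix_name = "PAM250",
                               min_score_fraction = 0.5) {
  q <- if (is.data.frame(query)) query$residues[1] else as.character(query)
  r <- if (is.data.frame(reference)) reference$residues[1] else as.character(reference)
  qid <- if (is.data.frame(query)) query$id[1] else "query"
  rid <- if (is.data.frame(reference)) reference$id[1] else "reference"
  n <- nchar(q); m <- nchar(r)
  if (window %% 2 != 1 || window < 3)
    sir_stop("window must be odd and >= 3, got ", window)
  if (window > min(n, m))
    sir_stop("window (", window, ") exceeds a sequence length (",
             min(n, m), ")")
  if (!(min_score_fraction > 0 && min_score_fraction <= 1))
    sir_stop("min_score_fraction must be in (0, 1]")
  sub <- score_matrix(matrix_name)
  qc <- seq_chars(q); rc <- seq_chars(r)
  if (any(!qc %in% rownames(sub)) || any(!rc %in% rownames(sub)))
    sir_stop("sequence contains residues absent from ", matrix_name)
  s <- sub[qc, rc, drop = FALSE]           # n x m position scores
  h <- (window - 1L) %/% 2L
  qi <- (h + 1L):(n - h); ri <- (h + 1L):(m - h)
  W <- matrix(0, length(qi), length(ri))
  for (k in -h:h) W <- W + s[qi + k, ri + k, drop = FALSE]
  qself_full <- sub[cbind(qc, qc)]
  rself_full <- sub[cbind(rc, rc)]
  roll <- function(v, w) {
    cs <- cumsum(c(0, v))
    cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
  }
  qself <- roll(qself_full, window)        # indexed by center qi
  rself <- roll(rself_full, window)
  thr <- outer(qself, rself, pmin) * min_score_fraction
  hit <- which(W >= thr, arr.ind = TRUE)
  marks <- cbind(query_center = qi[hit[, 1]] - 1L,
                 ref_center = ri[hit[, 2]] - 1L)
  structure(list(query_id = qid, reference_id = rid, window = window,
                 matrix_name = matrix_name,
                 min_score_fraction = min_score_fraction,
                 n_query = n, n_ref = m,
                 marks = marks, scores = W,
                 query_centers = qi - 1L, ref_centers = ri - 1L),
            class = "sir_dotmatrix")
}

#' @export
print.sir_dotmatrix <- function(x, ...) {
  cat("Dot matrix", x$query_id, "vs", x$reference_id,
      sprintf("(window %d, %s, threshold %.2f): %d marks\n",
              x$window, x$matrix_name, x$min_score_fraction, nrow(x$marks)))
  invisible(x)
}

#' Dump dot-matrix marks as a TSV
#' @param dm a `sir_dotmatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot_matrix_tsv <- function(dm, path) {
  utils::write.table(as.data.frame(dm$marks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
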