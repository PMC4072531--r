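# Extraction of the inter-domain linker between two conserved catalytic
# anchors (e.g. the ERS C-terminus and PRS N-terminus flanking the
# WHEP-repeat linker of EPRS).

#' Extract the linker region between two conserved anchors
#'
#' Finds the best local-alignment footprint of each anchor in the full
#' protein and returns the region strictly between the end of the first
#' (ERS-side) footprint and the start of the second (PRS-side) footprint.
#' Each anchor alignment must reach `min_score_fraction` of the anchor's
#' perfect self-match score.
#'
#' @param protein single-row protein [sir_seqs] or string.
#' @param ers_anchor,prs_anchor anchor sequences (>= 30 residues).
#' @param matrix_name scoring matrix for the local alignments.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param min_score_fraction required fraction of each anchor's self-score.
#' @return a `sir_linker`: list with `protein_id`, 0-based half-open
#'   `start`/`end` in the protein, and the linker `sequence`.
#' @export
extract_linker <- function(protein, ers_anchor, prs_anchor,
                           matrix_name = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5,
                           min_score_fraction = 0.3) {
  p <- if (is.data.frame(protein)) protein$residues[1] else as.character(protein)
  pid <- if (is.data.frame(protein)) protein$id[1] else "protein"
  ers <- if (is.data.frame(ers_anchor)) ers_anchor$residues[1] else as.character(ers_anchor)
  prs <- if (is.data.frame(prs_anchor)) prs_anchor$residues[1] else as.character(prs_anchor)
  if (nchar(ers) < 30 || nchar(prs) < 30)
    sir_stop("anchors must be >= 30 residues")
  sub <- score_matrix(matrix_name)
  fit <- function(anchor, name) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(anchor), Biostrings::AAString(p),
      type = "local", substitutionMatrix = sub,
      gapOpening = gap_open, gapExtension = gap_extend)
    self <- sum(sub[cbind(seq_chars(anchor), seq_chars(anchor))])
    if (Biostrings::score(al) < min_score_fraction * self)
      sir_stop("anchor not found: ", name)
    c(start = Biostrings::start(Biostrings::subject(al)),
      end = Biostrings::end(Biostrings::subject(al)))   # 1-based inclusive
  }
  e <- fit(ers, "ERS")
  r <- fit(prs, "PRS")
  if (e["end"] >= r["start"])
    sir_stop("anchor footprints overlap or are out of order (ERS ends at ",
             e["end"], ", PRS starts at ", r["start"], ")")
  start0 <- unname(e["end"])          # 0-based start = 1-based end of ERS
  end0 <- unname(r["start"] - 1L)     # 0-based half-open end
  structure(list(protein_id = pid, start = start0, end = end0,
                 sequence = substr(p, start0 + 1L, end0)),
            class = "sir_linker")
}

#' @export
print.sir_linker <- function(x, ...) {
  cat(sprintf("Linker of %s: [%d, %d) length %d\n", x$protein_id,
              x$start, x$end, x$end - x$start))
  invisible(x)
}
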