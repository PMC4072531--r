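# Progressive multiple alignment of repeat units: NJ guide tree on pairwise
# alignment-score distances, then profile-profile merging with the same
# affine-gap kernel used for pairwise alignment.

profile_freqs <- function(m, letters) {
  # per-column residue frequencies over all rows; gaps contribute nothing
  f <- matrix(0, length(letters), ncol(m), dimnames = list(letters, NULL))
  for (i in seq_len(nrow(m))) {
    idx <- match(m[i, ], letters)
    ok <- !is.na(idx)
    f[cbind(idx[ok], which(ok))] <- f[cbind(idx[ok], which(ok))] + 1
  }
  f / nrow(m)
}

profile_align <- function(mA, mB, sub, gap_open, gap_extend) {
  letters <- rownames(sub)
  fA <- profile_freqs(mA, letters)
  fB <- profile_freqs(mB, letters)
  S <- t(fA) %*% sub %*% fB
  # end gaps are free in profile merging (length heterogeneity between
  # units should not drag terminal residues inward)
  res <- .gotoh_align(S, gap_open, gap_extend, TRUE)
  path <- res$path
  k <- nrow(path)
  out <- matrix("-", nrow(mA) + nrow(mB), k)
  for (t in seq_len(k)) {
    if (path[t, 1] > 0) out[seq_len(nrow(mA)), t] <- mA[, path[t, 1]]
    if (path[t, 2] > 0) out[nrow(mA) + seq_len(nrow(mB)), t] <- mB[, path[t, 2]]
  }
  rownames(out) <- c(rownames(mA), rownames(mB))
  out
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbor joining on pairwise alignment-score
#' distances (d = 1 - S_ab / min(S_aa, S_bb)), midpoint-roots it, and merges
#' profiles up the tree with the affine-gap kernel. Output row order follows
#' the input.
#'
#' @param units protein [sir_seqs] (or named character vector), >= 2 rows.
#' @param matrix_name,gap_open,gap_extend alignment parameters.
#' @return a `sir_alignment`.
#' @export
progressive_msa <- function(units, matrix_name = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  if (is.data.frame(units)) {
    seqs <- units$residues; ids <- units$id
  } else {
    seqs <- as.character(units)
    ids <- names(units)
    if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  }
  n <- length(seqs)
  if (n < 2) sir_stop("progressive_msa needs at least 2 sequences")
  if (any(!nzchar(seqs))) sir_stop("empty input sequence")
  sub0 <- score_matrix(matrix_name)
  sub <- matrix(as.numeric(sub0), nrow(sub0), ncol(sub0),
                dimnames = dimnames(sub0))
  if (n == 2) {
    pa <- global_pairwise_align(seqs[1], seqs[2], matrix_name,
                                gap_open, gap_extend)
    return(sir_alignment(ids, pa$alignment$rows))
  }
  self <- vapply(seqs, function(s) {
    ch <- seq_chars(s); sum(sub[cbind(ch, ch)])
  }, numeric(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sc <- global_pairwise_align(seqs[i], seqs[j], matrix_name,
                                gap_open, gap_extend)$score
    D[i, j] <- D[j, i] <- 1 - sc / min(self[i], self[j])
  }
  D <- D - min(D, 0)          # NJ needs nonnegative dissimilarities
  guide <- neighbor_joining(distance_matrix(ids, D))
  guide <- phangorn::midpoint(guide)
  merge_node <- function(node) {
    ntip <- length(guide$tip.label)
    if (node <= ntip) {
      m <- matrix(seq_chars(seqs[match(guide$tip.label[node], ids)]), nrow = 1)
      rownames(m) <- guide$tip.label[node]
      return(m)
    }
    ch <- guide$edge[guide$edge[, 1] == node, 2]
    prof <- merge_node(ch[1])
    for (c2 in ch[-1])
      prof <- profile_align(prof, merge_node(c2), sub, gap_open, gap_extend)
    prof
  }
  m <- merge_node(length(guide$tip.label) + 1L)
  m <- m[ids, , drop = FALSE]
  m <- m[, colSums(m != "-") > 0, drop = FALSE]
  sir_alignment(ids, apply(m, 1, paste, collapse = ""))
}

#' Sum-of-pairs score of an alignment
#'
#' Residue pairs score by the substitution matrix; each gap run in a pairwise
#' projection costs `gap_open + L * gap_extend`; gap-gap columns are ignored.
#' @param aln a `sir_alignment`.
#' @param matrix_name,gap_open,gap_extend scoring parameters.
#' @return total score over all row pairs.
#' @export
sum_of_pairs_score <- function(aln, matrix_name = "BLOSUM62",
                               gap_open = 10, gap_extend = 0.5) {
  m <- alignment_matrix(aln)
  sub <- score_matrix(matrix_name)
  n <- nrow(m)
  total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- m[i, ]; b <- m[j, ]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    res <- a != "-" & b != "-"
    total <- total + sum(sub[cbind(a[res], b[res])])
    gaps <- rle(a == "-")
    total <- total - sum(gap_open + gap_extend *
                           gaps$lengths[gaps$values])
    gaps <- rle(b == "-")
    total <- total - sum(gap_open + gap_extend *
                           gaps$lengths[gaps$values])
  }
  total
}

#' Import an externally produced alignment from aligned FASTA
#'
#' Adapter for substituting any multiple-alignment tool: reads gapped FASTA
#' and validates it as a `sir_alignment`.
#' @param path aligned-FASTA file.
#' @return a `sir_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(); rows <- character(); cur <- NULL
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      ids <- c(ids, strsplit(trimws(sub("^>", "", line)), "\\s+")[[1]][1])
      rows <- c(rows, "")
      cur <- length(rows)
    } else rows[cur] <- paste0(rows[cur], toupper(gsub("\\s", "", line)))
  }
  sir_alignment(ids, rows)
}

#' Write an alignment as aligned FASTA
#' @param aln a `sir_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(paste0(">", aln$ids[i]), con)
    s <- aln$rows[i]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}
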