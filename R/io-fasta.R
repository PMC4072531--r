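#' @useDynLib sirphylo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

PROTEIN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                      "F","P","S","T","W","Y","V","X","*")
NUCLEOTIDE_ALPHABET <- c("A","C","G","T","N")

sir_stop <- function(...) stop(..., call. = FALSE)

#' Create a sequence set
#'
#' The package-wide sequence container: a data frame with columns `id`,
#' `description` and `residues`, carrying an `alphabet` attribute
#' (`"protein"` or `"nucleotide"`).
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of sequences (one string each).
#' @param description optional free-text descriptions.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param validate check ids unique, residues nonempty and within alphabet.
#' @return a `sir_seqs` data frame.
#' @export
sir_seqs <- function(id, residues, description = rep("", length(id)),
                     alphabet = c("protein", "nucleotide"), validate = TRUE) {
  alphabet <- match.arg(alphabet)
  x <- data.frame(id = as.character(id),
                  description = as.character(description),
                  residues = toupper(as.character(residues)),
                  stringsAsFactors = FALSE)
  attr(x, "alphabet") <- alphabet
  class(x) <- c("sir_seqs", "data.frame")
  if (validate) validate_seqs(x)
  x
}

validate_seqs <- function(x) {
  alphabet <- attr(x, "alphabet")
  letters_ok <- if (identical(alphabet, "nucleotide")) NUCLEOTIDE_ALPHABET else PROTEIN_ALPHABET
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup))
    sir_stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(x$residues)))
    sir_stop("empty residues for id(s): ",
             paste(x$id[!nzchar(x$residues)], collapse = ", "))
  for (i in seq_len(nrow(x))) {
    ch <- strsplit(x$residues[i], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(ch), letters_ok)
    if (length(bad))
      sir_stop("illegal character(s) ", paste(bad, collapse = ""),
               " in sequence '", x$id[i], "' for alphabet ", alphabet)
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Ids are the first whitespace-delimited token of the header; the remainder
#' is kept as the description. Residues are validated against the declared
#' alphabet and duplicate ids are rejected.
#'
#' @param path file path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return a [sir_seqs] data frame.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) sir_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(); desc <- character(); seqs <- character()
  cur <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      header <- sub("^>", "", line)
      if (!nzchar(trimws(header)))
        sir_stop("malformed FASTA header at line ", ln, ": empty id")
      tok <- strsplit(trimws(header), "\\s+")[[1]]
      ids <- c(ids, tok[1])
      desc <- c(desc, if (length(tok) > 1) paste(tok[-1], collapse = " ") else "")
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      if (is.null(cur))
        sir_stop("FASTA parse error at line ", ln, ": sequence before header")
      chunk <- toupper(gsub("\\s", "", line))
      letters_ok <- if (alphabet == "nucleotide") NUCLEOTIDE_ALPHABET else PROTEIN_ALPHABET
      bad <- setdiff(unique(strsplit(chunk, "", fixed = TRUE)[[1]]), letters_ok)
      if (length(bad))
        sir_stop("illegal character(s) ", paste(bad, collapse = ""),
                 " at line ", ln, " for alphabet ", alphabet)
      seqs[cur] <- paste0(seqs[cur], chunk)
    }
  }
  if (!length(ids)) sir_stop("no FASTA records in ", path)
  sir_seqs(ids, seqs, desc, alphabet = alphabet)
}

#' Write a FASTA file
#'
#' Standard FASTA with a fixed 60-residue line wrap.
#'
#' @param records a [sir_seqs] data frame (nonempty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    sir_stop("write_fasta: empty record list")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a nucleotide sequence in the three forward frames
#'
#' Standard genetic code; the trailing partial codon is dropped and stop
#' codons are rendered as `*`. Codons containing `N` translate to `X`.
#' The frame is recorded in the description; frames too short to yield a
#' residue give an empty string flagged `(empty)`.
#'
#' @param nt a single-row nucleotide [sir_seqs] or a nucleotide string.
#' @param id identifier used when `nt` is a bare string.
#' @return a protein `sir_seqs` with three rows (frames +1, +2, +3).
#' @export
translate_three_frames <- function(nt, id = "seq") {
  if (is.data.frame(nt)) {
    stopifnot(nrow(nt) == 1)
    id <- nt$id[1]
    s <- nt$residues[1]
  } else s <- toupper(as.character(nt))
  if (nchar(s) < 3)
    sir_stop("sequence too short to translate in any frame (length ",
             nchar(s), ")")
  prot <- character(3)
  for (f in 1:3) {
    sub <- substr(s, f, nchar(s))
    keep <- nchar(sub) - nchar(sub) %% 3
    if (keep < 3) { prot[f] <- ""; next }
    dna <- Biostrings::DNAString(substr(sub, 1, keep))
    aa <- Biostrings::translate(dna, if.fuzzy.codon = "solve")
    aa <- as.character(aa)
    aa <- gsub("[^ARNDCQEGHILKMFPSTWYVX*]", "X", aa)
    prot[f] <- aa
  }
  if (!nzchar(prot[1]))
    sir_stop("frame +1 yields no residues")
  out <- data.frame(
    id = paste0(id, "_frame", 1:3),
    description = paste0("frame=+", 1:3, ifelse(nzchar(prot), "", " (empty)")),
    residues = prot, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- "protein"
  class(out) <- c("sir_seqs", "data.frame")
  out
}
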