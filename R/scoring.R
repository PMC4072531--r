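# Residue-level scoring matrices (PAM250, BLOSUM62, ...) from Biostrings.

.score_cache <- new.env(parent = emptyenv())

#' Fetch a residue substitution scoring matrix by name
#'
#' Looks the matrix up in the tables shipped with Biostrings (PAM30..PAM250,
#' BLOSUM45..BLOSUM100). Used by the dot-matrix scan and the global aligner.
#'
#' @param matrix_name e.g. `"PAM250"` or `"BLOSUM62"`.
#' @return an integer scoring matrix with residue dimnames.
#' @export
score_matrix <- function(matrix_name) {
  if (!is.character(matrix_name) || length(matrix_name) != 1)
    sir_stop("matrix_name must be a single string")
  if (!is.null(.score_cache[[matrix_name]])) return(.score_cache[[matrix_name]])
  ok <- try(suppressWarnings(utils::data(list = matrix_name,
                                         package = "Biostrings",
                                         envir = .score_cache)),
            silent = TRUE)
  if (inherits(ok, "try-error") || is.null(.score_cache[[matrix_name]]))
    sir_stop("unknown scoring matrix: ", matrix_name)
  .score_cache[[matrix_name]]
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
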