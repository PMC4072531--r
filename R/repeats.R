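# Automatic fixed-length repeat-unit boundary calling from dot-matrix runs,
# and two-stringency degenerate-repeat flagging.

new_repeat_units <- function(species, protein_id, start, score,
                             domain_length, linker, stringency) {
  n <- length(start)
  data.frame(species = rep(species, n), protein_id = rep(protein_id, n),
             ordinal = integer(n), start = as.integer(start),
             end = as.integer(start + domain_length),
             length = rep(as.integer(domain_length), n),
             degenerate = logical(n),
             stringency = rep(stringency, n),
             score = score,
             sequence = substr(rep(linker_seq_full(linker), n),
                               start - linker_offset(linker) + 1L,
                               start - linker_offset(linker) + domain_length),
             stringsAsFactors = FALSE)
}

linker_seq_full <- function(linker) {
  if (inherits(linker, "sir_linker")) linker$sequence else as.character(linker)
}
linker_offset <- function(linker) {
  if (inherits(linker, "sir_linker")) linker$start else 0L
}

#' Call fixed-length repeat-unit boundaries in a linker
#'
#' For each reference domain, computes a dot matrix of the linker against the
#' reference; every maximal diagonal run of marks nominates one candidate
#' placement of a `domain_length` window (the full-coverage placement on that
#' diagonal, scored by the summed ungapped substitution score). Candidates
#' are merged across references, overlaps are resolved in favour of the
#' higher-scoring unit (ties: earlier start), and ordinals are assigned from
#' the N terminus.
#'
#' @param linker a `sir_linker` (from [extract_linker()]) or a plain string;
#'   plain strings are treated as a linker starting at protein coordinate 0.
#' @param reference_domains protein [sir_seqs] (or character vector) of
#'   reference repeat domains, each exactly `domain_length` residues.
#' @param window,matrix_name,min_score_fraction dot-matrix parameters.
#' @param domain_length repeat-unit length (default 50).
#' @param species,protein_id metadata attached to the returned units.
#' @param stringency label recorded in the `stringency` column.
#' @return a `sir_repeats` data frame with 0-based half-open protein
#'   coordinates, ordinals increasing N->C, and unit sequences.
#' @export
call_repeat_boundaries <- function(linker, reference_domains, window = 11,
                                   matrix_name = "PAM250",
                                   min_score_fraction = 0.5,
                                   domain_length = 50,
                                   species = NA_character_,
                                   protein_id = NULL,
                                   stringency = "high") {
  lseq <- linker_seq_full(linker)
  off <- linker_offset(linker)
  if (is.null(protein_id))
    protein_id <- if (inherits(linker, "sir_linker")) linker$protein_id else "protein"
  refs <- if (is.data.frame(reference_domains)) reference_domains$residues
          else as.character(reference_domains)
  if (!length(refs)) sir_stop("at least one reference domain required")
  if (any(nchar(refs) != domain_length))
    sir_stop("reference domains must be exactly domain_length (",
             domain_length, ") residues")
  empty <- new_repeat_units(species, protein_id, integer(0), numeric(0),
                            domain_length, linker, stringency)
  L <- nchar(lseq)
  if (L == 0) return(finish_units(empty))
  if (domain_length > L) {
    warning("domain_length exceeds linker length; no units callable")
    return(finish_units(empty))
  }
  sub <- score_matrix(matrix_name)
  lch <- seq_chars(lseq)
  cand <- list()
  for (ref in refs) {
    if (window > min(L, nchar(ref))) next
    dm <- compute_dot_matrix(lseq, ref, window = window,
                             matrix_name = matrix_name,
                             min_score_fraction = min_score_fraction)
    if (!nrow(dm$marks)) next
    diags <- unique(dm$marks[, 1] - dm$marks[, 2])
    rch <- seq_chars(ref)
    rself <- sum(sub[cbind(rch, rch)])
    for (d in diags) {
      s0 <- max(0L, min(as.integer(d), L - domain_length))
      win <- lch[(s0 + 1):(s0 + domain_length)]
      sc <- sum(sub[cbind(win, rch)])
      # the stringency fraction applies at the unit scale too: the placed
      # window must reach the same fraction of the maximum attainable score,
      # which suppresses single-window chance hits
      wself <- sum(sub[cbind(win, win)])
      if (sc < min_score_fraction * min(rself, wself)) next
      cand[[length(cand) + 1L]] <- c(start = s0, score = sc)
    }
  }
  if (!length(cand)) return(finish_units(empty))
  cd <- do.call(rbind, cand)
  cd <- as.data.frame(cd)
  # best score per distinct start
  cd <- cd[order(cd$start, -cd$score), , drop = FALSE]
  cd <- cd[!duplicated(cd$start), , drop = FALSE]
  # overlap resolution: score desc, tie earlier start
  cd <- cd[order(-cd$score, cd$start), , drop = FALSE]
  chosen <- logical(0)
  sel <- integer(0)
  for (i in seq_len(nrow(cd))) {
    s <- cd$start[i]
    if (!any(abs(cd$start[sel] - s) < domain_length)) sel <- c(sel, i)
  }
  cd <- cd[sel, , drop = FALSE]
  units <- new_repeat_units(species, protein_id, cd$start + off, cd$score,
                            domain_length, linker, stringency)
  finish_units(units)
}

finish_units <- function(units) {
  units <- units[order(units$start), , drop = FALSE]
  units$ordinal <- seq_len(nrow(units))
  rownames(units) <- NULL
  class(units) <- c("sir_repeats", "data.frame")
  units
}

#' Detect repeats at two stringencies and flag degenerate units
#'
#' Runs the boundary caller at a high and a low dot-matrix stringency.
#' Units found only at low stringency are flagged `degenerate = TRUE`
#' (`stringency = "low"`); these are reported but excluded from the
#' non-overlap guarantee that holds among the high-stringency units.
#'
#' @param linker,reference_domains as in [call_repeat_boundaries()].
#' @param high_cfg,low_cfg lists with `window`, `matrix_name` and
#'   `min_score_fraction`; `low_cfg$min_score_fraction` must be smaller.
#' @param domain_length,species,protein_id as in [call_repeat_boundaries()].
#' @return a `sir_repeats` data frame, ordinal-sorted, with degenerate flags.
#' @export
detect_degenerate_repeats <- function(linker, reference_domains,
                                      high_cfg = list(window = 11,
                                                      matrix_name = "PAM250",
                                                      min_score_fraction = 0.5),
                                      low_cfg = list(window = 11,
                                                     matrix_name = "PAM250",
                                                     min_score_fraction = 0.3),
                                      domain_length = 50,
                                      species = NA_character_,
                                      protein_id = NULL) {
  if (!(low_cfg$min_score_fraction < high_cfg$min_score_fraction))
    sir_stop("low-stringency min_score_fraction must be below high-stringency")
  hi <- call_repeat_boundaries(linker, reference_domains,
                               window = high_cfg$window,
                               matrix_name = high_cfg$matrix_name,
                               min_score_fraction = high_cfg$min_score_fraction,
                               domain_length = domain_length,
                               species = species, protein_id = protein_id,
                               stringency = "high")
  lo <- call_repeat_boundaries(linker, reference_domains,
                               window = low_cfg$window,
                               matrix_name = low_cfg$matrix_name,
                               min_score_fraction = low_cfg$min_score_fraction,
                               domain_length = domain_length,
                               species = species, protein_id = protein_id,
                               stringency = "low")
  if (nrow(lo)) {
    overl <- vapply(seq_len(nrow(lo)), function(i) {
      any(lo$start[i] < hi$end & lo$end[i] > hi$start)
    }, logical(1))
    extra <- lo[!overl, , drop = FALSE]
    if (nrow(extra)) {
      extra$degenerate <- TRUE
      extra$stringency <- "low"
      hi <- rbind(hi, extra)
    }
  }
  finish_units(hi)
}

#' Write a repeat-unit table as TSV
#' @param units a `sir_repeats` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_tsv <- function(units, path) {
  utils::write.table(units, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Unit identifiers of repeat units
#'
#' Canonical leaf names used in repeat-level trees:
#' `species|protein_id|ordinal`.
#' @param units a `sir_repeats` data frame.
#' @return character vector of ids.
#' @export
repeat_unit_ids <- function(units) {
  paste(units$species, units$protein_id, units$ordinal, sep = "|")
}
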