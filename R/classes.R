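# Assignment of repeat units to sequence classes from the repeat tree, and
# species class-count profiles.

#' Assign repeat units to classes from a repeat-level tree
#'
#' Manual mode: each class is the smallest clade containing its anchor
#' leaves; the clades must be disjoint and cover all leaves. Automatic mode:
#' k-medoids (PAM) on patristic distances. Classes are labeled `a`, `b`,
#' `c`, ... in order of their alphabetically smallest member leaf, so labels
#' are deterministic.
#'
#' @param tree repeat-level [ape::phylo]; leaves are repeat-unit ids.
#' @param anchors named list of leaf-label vectors (manual mode), names are
#'   ignored in favour of the deterministic a/b/c labeling.
#' @param k number of classes (automatic mode).
#' @param seed RNG seed (kept for interface stability; PAM is deterministic).
#' @return a `sir_classes`: list with `labels` (named character vector
#'   leaf -> class) and `k`.
#' @export
assign_repeat_classes <- function(tree, anchors = NULL, k = NULL, seed = 1) {
  leaves <- tree$tip.label
  if (is.null(anchors) == is.null(k))
    sir_stop("give exactly one of anchors (manual) or k (automatic)")
  if (!is.null(anchors)) {
    clades <- lapply(anchors, function(a) {
      bad <- setdiff(a, leaves)
      if (length(bad))
        sir_stop("anchor leaves not in tree: ", paste(bad, collapse = ","))
      if (length(a) == 1) return(a)
      node <- ape::getMRCA(tree, a)
      ape::extract.clade(tree, node)$tip.label
    })
    for (i in seq_along(clades)) for (j in seq_along(clades)) {
      if (i >= j) next
      ov <- intersect(clades[[i]], clades[[j]])
      if (length(ov))
        sir_stop("anchor clades overlap; offending leaves: ",
                 paste(ov, collapse = ","))
    }
    uncovered <- setdiff(leaves, unlist(clades))
    if (length(uncovered))
      sir_stop("anchor clades do not cover all leaves; unlabeled: ",
               paste(uncovered, collapse = ","))
    groups <- clades
  } else {
    if (k < 1) sir_stop("k must be >= 1")
    if (k == 1) {
      groups <- list(leaves)
    } else {
      D <- stats::cophenetic(tree)[leaves, leaves]
      pm <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
      groups <- split(leaves, pm$clustering)
    }
  }
  groups <- groups[order(vapply(groups, min, character(1)))]
  lab <- character(0)
  for (g in seq_along(groups)) {
    nm <- class_letter(g)
    lab[groups[[g]]] <- nm
  }
  structure(list(labels = lab[leaves], k = length(groups)),
            class = "sir_classes")
}

class_letter <- function(i) {
  if (i <= 26) letters[i] else paste0(letters[(i - 1) %/% 26],
                                      letters[(i - 1) %% 26 + 1])
}

#' Species profiles over repeat classes
#'
#' Counts labeled units per (species, class). Degenerate units are excluded
#' by default, mirroring the exclusion of atypical repeats from groupings;
#' species with zero labeled units keep an explicit zero profile.
#'
#' @param labeling a `sir_classes` whose names are repeat-unit ids as
#'   produced by [repeat_unit_ids()].
#' @param units a `sir_repeats` table covering the labeled units.
#' @param species optional species universe (default: those in `units`);
#'   species without units get zero rows.
#' @param include_degenerate count degenerate units too.
#' @return a `sir_profiles`: integer matrix species x classes.
#' @export
build_species_profiles <- function(labeling, units, species = NULL,
                                   include_degenerate = FALSE) {
  ids <- repeat_unit_ids(units)
  lab <- labeling$labels
  keep <- names(lab) %in% ids
  lab <- lab[keep]
  sp_of <- units$species[match(names(lab), ids)]
  if (any(is.na(sp_of)))
    sir_stop("labeled unit(s) missing species metadata: ",
             paste(names(lab)[is.na(sp_of)], collapse = ","))
  if (!include_degenerate) {
    deg <- units$degenerate[match(names(lab), ids)]
    lab <- lab[!deg]; sp_of <- sp_of[!deg]
  }
  if (is.null(species)) species <- sort(unique(units$species))
  classes <- sort(unique(labeling$labels))
  M <- matrix(0L, length(species), length(classes),
              dimnames = list(species, classes))
  if (length(lab)) {
    tb <- table(factor(sp_of, levels = species),
                factor(lab, levels = classes))
    M[] <- as.integer(tb)
  }
  structure(M, class = c("sir_profiles", "matrix"))
}

#' Write species profiles as a long-format TSV
#' @param profiles a `sir_profiles` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  long <- data.frame(species = rep(rownames(profiles), ncol(profiles)),
                     class = rep(colnames(profiles),
                                 each = nrow(profiles)),
                     count = as.integer(profiles))
  long <- long[order(long$species, long$class), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
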