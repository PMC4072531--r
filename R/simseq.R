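# Forward simulator, part 2: sequence evolution along the unit genealogy
# with tiered rates (slow flanks, moderate domains, fast spacers), and
# dataset emission with slice-exact truth coordinates.

rand_spacer <- function(model, cfg) {
  len <- sample(cfg$spacer_min:cfg$spacer_max, 1)
  stationary_sequence(model, len)
}

#' Evolve protein sequences over a simulated repeat history
#'
#' Root sequences are drawn from the model's stationary frequencies: two
#' conserved catalytic-domain stubs (flanks), a leading spacer, one ancestral
#' domain per root class (each separated from a shared ancestral domain by
#' `class_divergence` expected substitutions per site), and one spacer per
#' unit. Sequences then evolve down the species tree, each tier at
#' `subs_scale` times its relative rate; duplications copy the parent domain
#' and draw a fresh spacer; class-founding copies additionally receive
#' `burst_factor` extra expected substitutions at birth. Leaf proteins are
#' flank - spacer/domain alternation - flank, with unit coordinates recorded.
#'
#' @param truth a `sir_simtruth` from [simulate_repeat_evolution()].
#' @param model a `sir_model` (needs stationary frequencies).
#' @param cfg the `sir_simconfig` used for the truth (rates, lengths).
#' @return a `sir_simdata`: list with `proteins` (a [sir_seqs], one per
#'   species), `units` (truth table: species, protein_id, unit_id, class,
#'   ordinal, 0-based half-open start/end, sequence), `root_domains`
#'   (class -> ancestral domain string), `flanks`, `truth`.
#' @export
evolve_sequences <- function(truth, model, cfg = truth$config) {
  force(truth); force(cfg)          # evaluate before touching the RNG
  if (is.null(model$frequencies)) sir_stop("model lacks frequencies")
  set.seed(cfg$seed + 1000003L)
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  d_dom <- cfg$subs_scale * cfg$rate_domain
  d_spc <- cfg$subs_scale * cfg$rate_spacer
  d_flk <- cfg$subs_scale * cfg$rate_flank
  anc_dom <- stationary_sequence(model, cfg$domain_length)
  root_classes <- unique(truth$root_architecture$class)
  root_domains <- stats::setNames(
    vapply(root_classes, function(cl)
      evolve_string(model, anc_dom, cfg$class_divergence), character(1)),
    root_classes)
  state0 <- list(
    flankL = stationary_sequence(model, cfg$flank_length),
    flankR = stationary_sequence(model, cfg$flank_length),
    lead = rand_spacer(model, cfg),
    units = truth$root_architecture$unit_id,
    useq = as.list(stats::setNames(
      vapply(truth$root_architecture$class, function(cl) root_domains[[cl]],
             character(1)),
      truth$root_architecture$unit_id)),
    spacer = as.list(stats::setNames(
      vapply(truth$root_architecture$unit_id,
             function(u) rand_spacer(model, cfg), character(1)),
      truth$root_architecture$unit_id)))
  node_name <- function(node) {
    if (node <= ntip) tree$tip.label[node] else sprintf("n%d", node)
  }
  evolve_state <- function(st, dt) {
    if (dt <= 0) return(st)
    st$flankL <- evolve_string(model, st$flankL, dt * d_flk)
    st$flankR <- evolve_string(model, st$flankR, dt * d_flk)
    st$lead <- evolve_string(model, st$lead, dt * d_spc)
    for (u in st$units) {
      st$useq[[u]] <- evolve_string(model, st$useq[[u]], dt * d_dom)
      st$spacer[[u]] <- evolve_string(model, st$spacer[[u]], dt * d_spc)
    }
    st
  }
  run_branch <- function(st, branch, blen) {
    ev <- truth$events[truth$events$branch == branch, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    t <- 0
    for (i in seq_len(nrow(ev))) {
      st <- evolve_state(st, ev$time[i] - t)
      t <- ev$time[i]
      if (ev$event[i] == "loss") {
        u <- ev$unit[i]
        st$units <- setdiff(st$units, u)
        st$useq[[u]] <- NULL
        st$spacer[[u]] <- NULL
      } else {
        par <- ev$parent_unit[i]
        uid <- ev$unit[i]
        seqv <- st$useq[[par]]
        if (ev$event[i] == "innov")
          seqv <- evolve_string(model, seqv, cfg$burst_factor)
        at <- match(par, st$units)
        st$units <- append(st$units, uid, after = at)
        st$useq[[uid]] <- seqv
        st$spacer[[uid]] <- rand_spacer(model, cfg)
      }
    }
    evolve_state(st, blen - t)
  }
  proteins <- list()
  unit_rows <- list()
  recurse <- function(node, st) {
    kids <- which(tree$edge[, 1] == node)
    if (!length(kids)) {
      sp <- tree$tip.label[node]
      seq_parts <- c(st$flankL, st$lead)
      pos <- nchar(st$flankL) + nchar(st$lead)
      ord <- 0L
      for (u in st$units) {
        ord <- ord + 1L
        useq <- st$useq[[u]]
        unit_rows[[length(unit_rows) + 1L]] <<- data.frame(
          species = sp, protein_id = sp, unit_id = u,
          class = truth$genealogy[[u]]$class, ordinal = ord,
          start = pos, end = pos + nchar(useq), sequence = useq,
          stringsAsFactors = FALSE)
        seq_parts <- c(seq_parts, useq, st$spacer[[u]])
        pos <- pos + nchar(useq) + nchar(st$spacer[[u]])
      }
      seq_parts <- c(seq_parts, st$flankR)
      proteins[[sp]] <<- paste(seq_parts, collapse = "")
      return(invisible())
    }
    for (e in kids) {
      child <- tree$edge[e, 2]
      recurse(child, run_branch(st, node_name(child),
                                tree$edge.length[e]))
    }
  }
  recurse(ntip + 1L, state0)
  units <- if (length(unit_rows)) do.call(rbind, unit_rows)
           else data.frame(species = character(0), protein_id = character(0),
                           unit_id = character(0), class = character(0),
                           ordinal = integer(0), start = integer(0),
                           end = integer(0), sequence = character(0),
                           stringsAsFactors = FALSE)
  prot <- sir_seqs(names(proteins), unlist(proteins),
                   rep("simulated repeat protein", length(proteins)))
  structure(list(proteins = prot, units = units,
                 root_domains = root_domains,
                 flanks = list(left = state0$flankL, right = state0$flankR),
                 truth = truth),
            class = "sir_simdata")
}

#' Emit a simulated dataset to disk
#'
#' Writes `proteins.faa`, `species_tree.nwk`, `truth_units.tsv` and
#' `truth_events.tsv`. Truth coordinates are verified against the FASTA
#' slices before anything is written; a mismatch raises an
#' internal-consistency error.
#'
#' @param out_dir output directory (created if needed).
#' @param simdata a `sir_simdata` from [evolve_sequences()].
#' @return `out_dir`, invisibly.
#' @export
emit_dataset <- function(out_dir, simdata) {
  u <- simdata$units
  res <- stats::setNames(simdata$proteins$residues, simdata$proteins$id)
  for (i in seq_len(nrow(u))) {
    slice <- substr(res[[u$species[i]]], u$start[i] + 1L, u$end[i])
    if (!identical(slice, u$sequence[i]))
      sir_stop("internal consistency error: unit ", u$unit_id[i],
               " coordinates do not match the emitted protein")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(simdata$proteins, file.path(out_dir, "proteins.faa"))
  write_newick(simdata$truth$tree, file.path(out_dir, "species_tree.nwk"))
  utils::write.table(u, file.path(out_dir, "truth_units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(simdata$truth$events,
                     file.path(out_dir, "truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' True species profiles from simulated truth
#'
#' Per-leaf counts of units per class, straight from the simulator's
#' architectures (no detection step).
#' @param truth a `sir_simtruth`.
#' @return a `sir_profiles` matrix.
#' @export
true_species_profiles <- function(truth) {
  species <- names(truth$architectures)
  classes <- truth$classes
  M <- matrix(0L, length(species), length(classes),
              dimnames = list(species, classes))
  for (sp in species) {
    tb <- table(factor(truth$architectures[[sp]]$class, levels = classes))
    M[sp, ] <- as.integer(tb)
  }
  structure(M, class = c("sir_profiles", "matrix"))
}
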