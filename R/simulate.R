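# Forward simulator, part 1: configuration, species trees, and repeat-domain
# birth-death evolution along the tree (tandem duplication, loss, and
# class-founding innovation), with a machine-readable event log.

#' Simulation configuration
#'
#' Defaults define the reference study conditions of the package's recovery
#' experiments: an 8-species clade, one ancestral repeat class, moderate
#' tandem-duplication pressure, rare loss and innovation, and the tiered
#' substitution rates (slow flanks, moderate domains, fast spacers).
#'
#' @param seed RNG seed.
#' @param n_species number of extant species (>= 2).
#' @param species_tree optional Newick string or [ape::phylo]; when given it
#'   is used as-is and the birth-death parameters are ignored.
#' @param speciation,extinction birth-death rates per lineage per unit time.
#' @param crown_age crown age for unconditioned forward simulation; when
#'   `NULL` the tree is conditioned on `n_species` by rejection sampling.
#' @param lambda_dup,lambda_loss,lambda_innov per-domain event rates per
#'   unit time (tandem duplication, loss, class-founding duplication).
#' @param burst_factor extra expected substitutions per site applied once to
#'   a class-founding copy at birth.
#' @param rate_flank,rate_domain,rate_spacer relative substitution rates of
#'   the three sequence tiers; the default ordering flank < domain < spacer
#'   is enforced (override with a warning).
#' @param subs_scale expected substitutions per site per unit time for a
#'   tier of relative rate 1.
#' @param domain_length repeat-unit length in residues.
#' @param spacer_min,spacer_max uniform bounds for spacer lengths.
#' @param flank_length length of each conserved catalytic-domain stub.
#' @param root_architecture character vector of ancestral repeat classes in
#'   N->C order (may be empty to simulate repeat-less roots).
#' @param class_divergence expected substitutions per site separating each
#'   root class from the shared ancestral domain sequence.
#' @return a `sir_simconfig` list.
#' @export
sim_config <- function(seed = 1, n_species = 8, species_tree = NULL,
                       speciation = 1, extinction = 0, crown_age = NULL,
                       lambda_dup = 0.3, lambda_loss = 0.1,
                       lambda_innov = 0.05, burst_factor = 0.5,
                       rate_flank = 0.1, rate_domain = 1, rate_spacer = 5,
                       subs_scale = 0.15, domain_length = 50,
                       spacer_min = 10, spacer_max = 40, flank_length = 60,
                       root_architecture = "a", class_divergence = 0.8) {
  rates <- c(lambda_dup, lambda_loss, lambda_innov, speciation, extinction,
             rate_flank, rate_domain, rate_spacer, subs_scale)
  if (any(rates < 0)) sir_stop("all rates must be >= 0")
  if (n_species < 2) sir_stop("n_species must be >= 2")
  if (!(rate_flank < rate_domain && rate_domain < rate_spacer))
    warning("tier rates do not satisfy flank < domain < spacer; ",
            "proceeding with the given ordering")
  structure(list(seed = seed, n_species = n_species,
                 species_tree = species_tree, speciation = speciation,
                 extinction = extinction, crown_age = crown_age,
                 lambda_dup = lambda_dup, lambda_loss = lambda_loss,
                 lambda_innov = lambda_innov, burst_factor = burst_factor,
                 rate_flank = rate_flank, rate_domain = rate_domain,
                 rate_spacer = rate_spacer, subs_scale = subs_scale,
                 domain_length = domain_length, spacer_min = spacer_min,
                 spacer_max = spacer_max, flank_length = flank_length,
                 root_architecture = root_architecture,
                 class_divergence = class_divergence),
            class = "sir_simconfig")
}

#' High-signal preset for species-topology recovery experiments
#'
#' A fixed balanced 8-species tree with long internal branches (so internal
#' edges carry repeat-count changes), three pre-diverged ancestral classes,
#' duplication/loss pressure sized for roughly two to four events per
#' internal branch, and rare innovation. Sequence divergence is kept inside
#' the detectable range of the dot-matrix caller.
#'
#' @param seed RNG seed.
#' @return a `sir_simconfig`.
#' @export
sim_config_easy <- function(seed = 1) {
  tree <- paste0("(((s1:0.5,s2:0.5):1.3,(s3:0.5,s4:0.5):1.3):1.3,",
                 "((s5:0.5,s6:0.5):1.3,(s7:0.5,s8:0.5):1.3):1.3);")
  sim_config(seed = seed, n_species = 8, species_tree = tree,
             lambda_dup = 0.4, lambda_loss = 0.1, lambda_innov = 0.03,
             burst_factor = 0.3, subs_scale = 0.1,
             root_architecture = c("a", "b", "c"), class_divergence = 0.8)
}

yule_forward <- function(speciation, extinction, crown_age) {
  # Gillespie forward from 2 crown lineages; returns list of leaf birth
  # times etc. encoded as an ape tree; extinct lineages are pruned
  id <- 0L
  new_id <- function() { id <<- id + 1L; id }
  # lineage: list(start_time, name); build newick recursively by simulating
  sim_lineage <- function(t0) {
    t <- t0
    repeat {
      rate <- speciation + extinction
      if (rate <= 0) {
        return(list(text = sprintf("L%d:%g", new_id(), crown_age - t0),
                    alive = TRUE))
      }
      wait <- stats::rexp(1, rate)
      if (t + wait >= crown_age) {
        return(list(text = sprintf("L%d:%g", new_id(), crown_age - t0),
                    alive = TRUE))
      }
      t <- t + wait
      if (stats::runif(1) < speciation / rate) {
        a <- sim_lineage(t)
        b <- sim_lineage(t)
        if (a$alive && b$alive)
          return(list(text = sprintf("(%s,%s):%g", a$text, b$text, t - t0),
                      alive = TRUE))
        if (a$alive)
          return(list(text = add_len(a$text, t - t0), alive = TRUE))
        if (b$alive)
          return(list(text = add_len(b$text, t - t0), alive = TRUE))
        return(list(text = "", alive = FALSE))
      } else {
        return(list(text = "", alive = FALSE))
      }
    }
  }
  a <- sim_lineage(0)
  b <- sim_lineage(0)
  if (!a$alive || !b$alive) return(NULL)   # crown lineage died out
  ape::read.tree(text = sprintf("(%s,%s);", a$text, b$text))
}

add_len <- function(newick_frag, extra) {
  # add `extra` to the outermost branch length of a fragment
  pos <- regexpr(":[0-9.eE+-]+$", newick_frag)
  len <- as.numeric(substring(newick_frag, pos + 1))
  paste0(substring(newick_frag, 1, pos - 1), sprintf(":%g", len + extra))
}

#' Simulate (or pass through) an ultrametric species tree
#'
#' With `cfg$species_tree` set, that tree is returned unchanged. With
#' `cfg$crown_age` set, a birth-death process is run forward from two crown
#' lineages for that time (leaf count random). Otherwise trees are drawn
#' until one has exactly `cfg$n_species` extant leaves (bounded retries);
#' leaves are renamed s1..sn.
#'
#' @param cfg a `sir_simconfig`.
#' @param max_tries rejection-sampling bound.
#' @return an [ape::phylo].
#' @export
simulate_species_tree <- function(cfg, max_tries = 10000) {
  if (!is.null(cfg$species_tree)) {
    tr <- cfg$species_tree
    if (is.character(tr)) tr <- ape::read.tree(text = tr)
    return(tr)
  }
  if (!is.null(cfg$crown_age)) {
    for (i in seq_len(max_tries)) {
      tr <- yule_forward(cfg$speciation, cfg$extinction, cfg$crown_age)
      if (!is.null(tr)) return(tr)
    }
    sir_stop("no surviving crown clade in ", max_tries, " tries; ",
             "reduce extinction or crown_age")
  }
  # condition on n by rejection with a self-scaled crown age
  age <- log(cfg$n_species / 2) / max(cfg$speciation - cfg$extinction, 0.1)
  age <- max(age, 0.5)
  for (i in seq_len(max_tries)) {
    tr <- yule_forward(cfg$speciation, cfg$extinction, age)
    if (!is.null(tr) && length(tr$tip.label) == cfg$n_species) {
      tr$tip.label <- paste0("s", seq_along(tr$tip.label))
      return(tr)
    }
  }
  sir_stop("could not draw a tree with ", cfg$n_species, " leaves in ",
           max_tries, " tries; adjust speciation/extinction")
}

#' Simulate repeat-domain birth-death evolution along a species tree
#'
#' Gillespie simulation along each branch: every extant domain independently
#' undergoes tandem duplication (a copy of the same class inserted next to
#' its parent), loss, or class-founding duplication (a copy founding a new
#' class) at the configured rates. Returns the per-leaf ordered
#' architectures plus the full truth log (events, unit genealogy).
#'
#' @param tree species tree ([ape::phylo]).
#' @param cfg a `sir_simconfig`; the RNG is seeded from `cfg$seed`.
#' @return a `sir_simtruth`: list with `tree`, `architectures` (per leaf:
#'   data frame unit_id/class), `events` (branch, time, event, unit, class,
#'   parent_unit), `genealogy` (unit -> parent unit), `root_architecture`,
#'   `classes` (all class labels founded), `config`.
#' @export
simulate_repeat_evolution <- function(tree, cfg) {
  set.seed(cfg$seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  env <- new.env()
  env$unit_seq <- 0L
  env$class_seq <- length(cfg$root_architecture)
  env$events <- list()
  env$genealogy <- list()
  env$archs <- list()
  fresh_unit <- function(class, parent) {
    env$unit_seq <- env$unit_seq + 1L
    id <- sprintf("u%d", env$unit_seq)
    env$genealogy[[id]] <- list(parent = parent, class = class)
    id
  }
  root_arch <- data.frame(unit_id = character(0), class = character(0),
                          stringsAsFactors = FALSE)
  for (cl in cfg$root_architecture)
    root_arch <- rbind(root_arch,
                       data.frame(unit_id = fresh_unit(cl, NA_character_),
                                  class = cl, stringsAsFactors = FALSE))
  total_rate_per_unit <- cfg$lambda_dup + cfg$lambda_loss + cfg$lambda_innov
  evolve_branch <- function(arch, branch_name, blen) {
    t <- 0
    repeat {
      n <- nrow(arch)
      if (n == 0 || total_rate_per_unit == 0) break
      wait <- stats::rexp(1, total_rate_per_unit * n)
      if (t + wait > blen) break
      t <- t + wait
      i <- sample.int(n, 1)
      ev <- sample(c("dup", "loss", "innov"), 1,
                   prob = c(cfg$lambda_dup, cfg$lambda_loss,
                            cfg$lambda_innov))
      if (ev == "loss") {
        env$events[[length(env$events) + 1L]] <-
          data.frame(branch = branch_name, time = t, event = "loss",
                     unit = arch$unit_id[i], class = arch$class[i],
                     parent_unit = NA_character_, stringsAsFactors = FALSE)
        arch <- arch[-i, , drop = FALSE]
      } else {
        cls <- if (ev == "dup") arch$class[i] else {
          env$class_seq <- env$class_seq + 1L
          class_letter(env$class_seq)
        }
        uid <- fresh_unit(cls, arch$unit_id[i])
        env$events[[length(env$events) + 1L]] <-
          data.frame(branch = branch_name, time = t, event = ev,
                     unit = uid, class = cls,
                     parent_unit = arch$unit_id[i], stringsAsFactors = FALSE)
        top <- if (i == 0) arch[0, ] else arch[seq_len(i), , drop = FALSE]
        bot <- if (i >= nrow(arch)) arch[0, ]
               else arch[(i + 1):nrow(arch), , drop = FALSE]
        arch <- rbind(top,
                      data.frame(unit_id = uid, class = cls,
                                 stringsAsFactors = FALSE),
                      bot)
      }
    }
    arch
  }
  node_name <- function(node) {
    if (node <= ntip) tree$tip.label[node] else sprintf("n%d", node)
  }
  recurse <- function(node, arch) {
    kids <- which(tree$edge[, 1] == node)
    if (!length(kids)) {
      env$archs[[tree$tip.label[node]]] <- arch
      return(invisible())
    }
    for (e in kids) {
      child <- tree$edge[e, 2]
      carch <- evolve_branch(arch, node_name(child), tree$edge.length[e])
      recurse(child, carch)
    }
  }
  recurse(root, root_arch)
  events <- if (length(env$events)) do.call(rbind, env$events)
            else data.frame(branch = character(0), time = numeric(0),
                            event = character(0), unit = character(0),
                            class = character(0),
                            parent_unit = character(0),
                            stringsAsFactors = FALSE)
  classes <- sort(unique(c(cfg$root_architecture,
                           vapply(env$genealogy, function(g) g$class,
                                  character(1)))))
  structure(list(tree = tree, architectures = env$archs,
                 events = events, genealogy = env$genealogy,
                 root_architecture = root_arch, classes = classes,
                 config = cfg),
            class = "sir_simtruth")
}

#' Architectures at every node of the simulated history
#'
#' Replays the event log and returns the ordered architecture at each node
#' (leaves by tip label, internal nodes as `n<number>`), plus each node's
#' parent. Useful for leave-one-out experiments that need the true ancestral
#' repeat profile of a species.
#'
#' @param truth a `sir_simtruth`.
#' @return list with `architectures` (named list of data frames) and
#'   `parent` (named character vector node -> parent node).
#' @export
node_architectures <- function(truth) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  node_name <- function(node) {
    if (node <= ntip) tree$tip.label[node] else sprintf("n%d", node)
  }
  archs <- list()
  parent <- character(0)
  apply_events <- function(arch, branch) {
    ev <- truth$events[truth$events$branch == branch, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      if (ev$event[i] == "loss") {
        arch <- arch[arch$unit_id != ev$unit[i], , drop = FALSE]
      } else {
        at <- match(ev$parent_unit[i], arch$unit_id)
        top <- arch[seq_len(at), , drop = FALSE]
        bot <- if (at >= nrow(arch)) arch[0, ]
               else arch[(at + 1):nrow(arch), , drop = FALSE]
        arch <- rbind(top,
                      data.frame(unit_id = ev$unit[i], class = ev$class[i],
                                 stringsAsFactors = FALSE),
                      bot)
      }
    }
    arch
  }
  recurse <- function(node, arch) {
    archs[[node_name(node)]] <<- arch
    kids <- which(tree$edge[, 1] == node)
    for (e in kids) {
      ch <- tree$edge[e, 2]
      parent[[node_name(ch)]] <<- node_name(node)
      recurse(ch, apply_events(arch, node_name(ch)))
    }
  }
  recurse(ntip + 1L, truth$root_architecture)
  list(architectures = archs, parent = parent)
}

#' Replay the event log from the root architecture
#'
#' Internal-consistency check: applies each branch's logged events in time
#' order down the species tree and returns the reconstructed leaf
#' architectures, which must equal the simulated ones.
#'
#' @param truth a `sir_simtruth`.
#' @return named list of leaf architecture data frames.
#' @export
replay_event_log <- function(truth) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  node_name <- function(node) {
    if (node <= ntip) tree$tip.label[node] else sprintf("n%d", node)
  }
  out <- list()
  apply_events <- function(arch, branch) {
    ev <- truth$events[truth$events$branch == branch, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      if (ev$event[i] == "loss") {
        arch <- arch[arch$unit_id != ev$unit[i], , drop = FALSE]
      } else {
        at <- match(ev$parent_unit[i], arch$unit_id)
        top <- arch[seq_len(at), , drop = FALSE]
        bot <- if (at >= nrow(arch)) arch[0, ]
               else arch[(at + 1):nrow(arch), , drop = FALSE]
        arch <- rbind(top,
                      data.frame(unit_id = ev$unit[i], class = ev$class[i],
                                 stringsAsFactors = FALSE),
                      bot)
      }
    }
    arch
  }
  recurse <- function(node, arch) {
    kids <- which(tree$edge[, 1] == node)
    if (!length(kids)) {
      out[[tree$tip.label[node]]] <<- arch
      return(invisible())
    }
    for (e in kids)
      recurse(tree$edge[e, 2],
              apply_events(arch, node_name(tree$edge[e, 2])))
  }
  recurse(ntip + 1L, truth$root_architecture)
  out
}
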