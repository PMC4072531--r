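# Parsimonious collapse of species class-count profiles into a putative
# species tree: minimum Steiner tree in the unit-step (L1) profile lattice,
# with candidate Steiner points restricted to the Hanan grid, exact
# Dreyfus-Wagner search for small terminal sets, and predicted intermediate
# profiles on expanded edges.

#' Unit-step edit distance between two class-count profiles
#'
#' Minimum number of single-domain steps (duplication +1 on a class with a
#' copy present, loss -1, or class-founding innovation +1 into an empty
#' class) transforming one profile into the other. Under unit costs this is
#' the L1 distance over the union of class indices.
#'
#' @param u,v named nonnegative integer vectors (class -> count).
#' @return nonnegative integer.
#' @export
profile_edit_distance <- function(u, v) {
  if (any(u < 0) || any(v < 0)) sir_stop("negative counts")
  classes <- union(names(u), names(v))
  if (is.null(classes)) {
    if (length(u) != length(v)) sir_stop("unnamed profiles of unequal length")
    return(sum(abs(u - v)))
  }
  uu <- stats::setNames(rep(0, length(classes)), classes)
  vv <- uu
  uu[names(u)] <- u
  vv[names(v)] <- v
  sum(abs(uu - vv))
}

profile_key <- function(p) paste(p, collapse = ",")

unit_steps_between <- function(p, q, classes) {
  # deterministic unit-step chain p -> q: gains (duplication/innovation)
  # before losses, classes in sorted order, so intermediates never pass
  # through transiently repeat-less states
  steps <- list()
  deltas <- q - p
  ord <- order(deltas < 0, classes)      # gains (positive) first
  cur <- p
  for (ci in ord) {
    d <- deltas[ci]
    if (d == 0) next
    stp <- sign(d)
    for (r in seq_len(abs(d))) {
      nxt <- cur
      nxt[ci] <- nxt[ci] + stp
      ev <- if (stp < 0) "loss" else if (cur[ci] == 0) "innov" else "dup"
      steps[[length(steps) + 1L]] <- list(from = cur, to = nxt,
                                          event = ev, class = classes[ci])
      cur <- nxt
    }
  }
  steps
}

l1_dist_matrix <- function(G) {
  # G: nodes x classes matrix
  n <- nrow(G)
  D <- matrix(0, n, n)
  for (ci in seq_len(ncol(G)))
    D <- D + abs(outer(G[, ci], G[, ci], "-"))
  D
}

dreyfus_wagner <- function(D, term_idx) {
  # exact minimum Steiner tree of terminals term_idx over the candidate node
  # set with distance matrix D; returns list(cost, edges = 2-col matrix of
  # node indices)
  nterm <- length(term_idx)
  if (nterm == 1) return(list(cost = 0, edges = matrix(0L, 0, 2)))
  t0 <- term_idx[nterm]
  base <- term_idx[-nterm]
  nb <- length(base)
  nsub <- bitwShiftL(1L, nb) - 1L
  nV <- nrow(D)
  dp <- matrix(Inf, nsub, nV)
  # choice bookkeeping for backtracking:
  # type 1: dp[S,v] = d(v, w) + dpm[S, w]    (w recorded)
  # type 0: singleton S = {t}: edge v -- t
  choice_w <- matrix(NA_integer_, nsub, nV)
  choice_split <- matrix(NA_integer_, nsub, nV)
  singles <- bitwShiftL(1L, seq_len(nb) - 1L)
  for (i in seq_len(nb)) dp[singles[i], ] <- D[base[i], ]
  subset_order <- order(vapply(seq_len(nsub), function(S)
    sum(bitwAnd(S, singles) > 0), numeric(1)))
  for (S in subset_order) {
    if (S %in% singles) next
    # proper nonempty subset split at each node
    dpm <- rep(Inf, nV)
    split_at <- rep(NA_integer_, nV)
    S1 <- bitwAnd(S - 1L, S)
    while (S1 > 0L) {
      S2 <- S - S1
      if (S1 < S2) {            # enumerate unordered splits once
        cand <- dp[S1, ] + dp[S2, ]
        better <- cand < dpm
        dpm[better] <- cand[better]
        split_at[better] <- S1
      }
      S1 <- bitwAnd(S1 - 1L, S)
    }
    for (v in seq_len(nV)) {
      cand <- D[v, ] + dpm
      w <- which.min(cand)
      dp[S, v] <- cand[w]
      choice_w[S, v] <- w
      choice_split[S, v] <- split_at[w]
    }
  }
  full <- nsub
  edges <- list()
  add_path <- function(a, b) {
    if (a != b) edges[[length(edges) + 1L]] <<- c(a, b)
  }
  expand <- function(S, v) {
    if (S %in% singles) {
      t <- base[match(S, singles)]
      add_path(v, t)
      return(invisible())
    }
    w <- choice_w[S, v]
    sp <- choice_split[S, v]
    add_path(v, w)
    expand(sp, w)
    expand(S - sp, w)
  }
  if (nb == 0) return(list(cost = 0, edges = matrix(0L, 0, 2)))
  cost <- dp[full, t0]
  expand(full, t0)
  em <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  list(cost = cost, edges = em)
}

greedy_steiner <- function(D, term_idx) {
  # shortest-path-insertion heuristic: grow the tree by repeatedly attaching
  # the terminal closest to any node already in the tree
  remaining <- term_idx
  inside <- remaining[1]
  remaining <- remaining[-1]
  edges <- list()
  cost <- 0
  while (length(remaining)) {
    sub <- D[inside, remaining, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- inside[ij[1]]; b <- remaining[ij[2]]
    edges[[length(edges) + 1L]] <- c(a, b)
    cost <- cost + D[a, b]
    inside <- c(inside, b)
    remaining <- setdiff(remaining, b)
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  list(cost = cost, edges = em)
}

prim_mst <- function(D, nodes) {
  # deterministic Prim MST over the given node indices; returns
  # list(cost, edges) with edges as global node-index pairs
  n <- length(nodes)
  if (n < 2) return(list(cost = 0, edges = matrix(0L, 0, 2)))
  Dm <- D[nodes, nodes, drop = FALSE]
  intree <- 1L
  dmin <- Dm[1, ]
  via <- rep(1L, n)
  edges <- matrix(0L, n - 1, 2)
  cost <- 0
  for (it in seq_len(n - 1)) {
    dmin[intree] <- Inf
    j <- which.min(dmin)
    edges[it, ] <- c(nodes[via[j]], nodes[j])
    cost <- cost + dmin[j]
    intree <- c(intree, j)
    upd <- Dm[j, ] < dmin
    via[upd] <- j
    dmin <- pmin(dmin, Dm[j, ])
  }
  list(cost = cost, edges = edges)
}

dollo_violations <- function(edges, G, classes) {
  # per class: number of extra connected components of the present-state
  # node set in the expanded unit-step tree (0 = single origin)
  nodes <- list()
  key_of <- function(p) profile_key(p)
  eadj <- list()
  add_edge <- function(p, q) {
    kp <- key_of(p); kq <- key_of(q)
    nodes[[kp]] <<- p; nodes[[kq]] <<- q
    eadj[[kp]] <<- c(eadj[[kp]], kq)
    eadj[[kq]] <<- c(eadj[[kq]], kp)
  }
  for (i in seq_len(nrow(edges))) {
    p <- G[edges[i, 1], ]; q <- G[edges[i, 2], ]
    for (s in unit_steps_between(p, q, classes)) add_edge(s$from, s$to)
  }
  if (!length(nodes)) return(0)
  total <- 0
  prof <- do.call(rbind, nodes)
  for (ci in seq_along(classes)) {
    present <- rownames(prof)[prof[, ci] > 0]
    if (length(present) < 2) next
    seen <- present[1]; queue <- present[1]
    comp <- 1
    left <- setdiff(present, seen)
    while (length(left)) {
      while (length(queue)) {
        x <- queue[1]; queue <- queue[-1]
        for (y in eadj[[x]]) if (y %in% left) {
          seen <- c(seen, y); left <- setdiff(left, y); queue <- c(queue, y)
        }
      }
      if (length(left)) {
        comp <- comp + 1
        queue <- left[1]; seen <- c(seen, left[1]); left <- left[-1]
      }
    }
    total <- total + comp - 1
  }
  total
}

dollo_refine <- function(res, G, D, term_idx, classes,
                         max_enum = 20000) {
  # among co-optimal Steiner node sets (exact instances only), prefer the
  # tree minimizing convergent class origins (Dollo violations), then the
  # one with fewest predicted nodes, then a deterministic key
  nV <- nrow(G)
  cand <- setdiff(seq_len(nV), term_idx)
  maxs <- max(length(term_idx) - 2L, 0L)
  n_comb <- sum(vapply(0:min(maxs, length(cand)), function(sz)
    choose(length(cand), sz), numeric(1)))
  if (n_comb > max_enum) return(res)
  best <- list(score = c(Inf, Inf), key = "", res = res)
  target <- res$cost + 1e-9
  for (sz in 0:min(maxs, length(cand))) {
    combs <- if (sz == 0) list(integer(0))
             else asplit(utils::combn(cand, sz), 2)
    for (cb in combs) {
      mst <- prim_mst(D, c(term_idx, as.integer(cb)))
      if (mst$cost > target) next
      viol <- dollo_violations(mst$edges, G, classes)
      npred <- length(setdiff(unique(as.integer(mst$edges)), term_idx))
      key <- paste(sort(apply(mst$edges, 1, paste, collapse = "-")),
                   collapse = ";")
      sc <- c(viol, npred)
      if (sc[1] < best$score[1] ||
          (sc[1] == best$score[1] &&
           (sc[2] < best$score[2] ||
            (sc[2] == best$score[2] && key < best$key)))) {
        best <- list(score = sc, key = key,
                     res = list(cost = mst$cost, edges = mst$edges))
      }
    }
  }
  best$res
}

#' Collapse species profiles into a putative species tree
#'
#' Connects the observed class-count profiles by a minimum-total-cost tree
#' in the unit-step lattice (each edge costs its L1 length; steps are
#' single-domain duplication, loss or innovation events). Candidate Steiner
#' points are restricted to the Hanan grid (cartesian product of observed
#' per-class counts). Up to `max_exact_terminals` distinct profiles the
#' exact Dreyfus-Wagner algorithm is used; above, a greedy insertion
#' heuristic (flagged in the output). Multi-step edges are expanded into
#' chains of unit-step nodes; nodes whose profile matches no observed
#' species are flagged predicted.
#'
#' @param profiles a `sir_profiles` matrix (species x classes), >= 2 species.
#' @param root_hint optional species name; its profile becomes the root and
#'   edge events are read parent -> child.
#' @param max_exact_terminals size bound for the exact search (default 6).
#' @return a `sir_collapsed`: list with `nodes` (data frame: id, profile
#'   key, predicted flag, species), `profiles` (node x class matrix),
#'   `edges` (parent, child, events string, cost), `total_cost`, `exact`,
#'   `rooted`.
#' @export
collapse_to_species_tree <- function(profiles, root_hint = NULL,
                                     max_exact_terminals = 6) {
  if (nrow(profiles) < 2) sir_stop("need >= 2 species profiles")
  classes <- colnames(profiles)
  keys <- apply(profiles, 1, profile_key)
  uniq <- !duplicated(keys)
  P <- profiles[uniq, , drop = FALSE]
  ukeys <- keys[uniq]
  spp_of <- lapply(ukeys, function(k) rownames(profiles)[keys == k])
  # Hanan grid over observed per-class count values
  vals <- lapply(seq_along(classes), function(ci) sort(unique(P[, ci])))
  G <- as.matrix(expand.grid(vals))
  colnames(G) <- classes
  gkeys <- apply(G, 1, profile_key)
  term_idx <- match(ukeys, gkeys)
  exact <- length(term_idx) <= max_exact_terminals
  # L1 step costs, plus an infinitesimal tie-break against routing through
  # the repeat-less (all-zero) profile as an ancestor
  D <- l1_dist_matrix(G)
  zero <- rowSums(G) == 0
  if (any(zero))
    D <- D + 1e-6 * (outer(zero, zero, "|") & D > 0)
  res <- if (exact) dreyfus_wagner(D, term_idx)
         else greedy_steiner(D, term_idx)
  if (exact)
    res <- dollo_refine(res, G, D, term_idx, classes)
  # drop zero-length edges (nodes coincide) by union-find relabeling
  parent_of <- seq_len(nrow(G))
  find <- function(x) { while (parent_of[x] != x) x <- parent_of[x]; x }
  em <- res$edges
  keep <- logical(nrow(em))
  for (i in seq_len(nrow(em))) {
    a <- find(em[i, 1]); b <- find(em[i, 2])
    if (gkeys[a] == gkeys[b]) {
      if (a != b) parent_of[b] <- a
    } else keep[i] <- TRUE
  }
  em <- em[keep, , drop = FALSE]
  em <- cbind(vapply(em[, 1], find, integer(1)),
              vapply(em[, 2], find, integer(1)))
  em <- unique(em)
  # expand multi-step edges into unit-step chains
  node_profiles <- list()
  node_id <- function(p) {
    k <- profile_key(p)
    if (!k %in% names(node_profiles))
      node_profiles[[k]] <<- p
    k
  }
  chain_edges <- list()
  for (i in seq_len(nrow(em))) {
    p <- G[em[i, 1], ]; q <- G[em[i, 2], ]
    steps <- unit_steps_between(p, q, classes)
    for (s in steps) {
      chain_edges[[length(chain_edges) + 1L]] <-
        list(from = node_id(s$from), to = node_id(s$to),
             event = sprintf("%s(%s)", s$event, s$class))
    }
  }
  if (!nrow(em)) node_id(G[term_idx[1], ])   # degenerate: all same profile
  segments <- data.frame(from = gkeys[em[, 1]], to = gkeys[em[, 2]],
                         stringsAsFactors = FALSE)
  nodes <- do.call(rbind, node_profiles)
  rownames(nodes) <- names(node_profiles)
  observed <- rownames(nodes) %in% ukeys
  species <- vapply(rownames(nodes), function(k) {
    i <- match(k, ukeys)
    if (is.na(i)) "" else paste(spp_of[[i]], collapse = ",")
  }, character(1))
  edges_df <- data.frame(
    parent = vapply(chain_edges, function(e) e$from, character(1)),
    child = vapply(chain_edges, function(e) e$to, character(1)),
    event = vapply(chain_edges, function(e) e$event, character(1)),
    stringsAsFactors = FALSE)
  rooted <- FALSE
  if (!is.null(root_hint)) {
    if (!root_hint %in% rownames(profiles))
      sir_stop("root_hint species not in profiles: ", root_hint)
    rootk <- keys[match(root_hint, rownames(profiles))]
    edges_df <- orient_edges(edges_df, rootk, classes, nodes)
    rooted <- TRUE
  }
  total_cost <- nrow(edges_df)
  structure(list(
    nodes = data.frame(id = rownames(nodes),
                       predicted = !observed, species = species,
                       stringsAsFactors = FALSE),
    profiles = nodes,
    edges = edges_df,
    segments = segments,
    classes = classes,
    total_cost = total_cost,
    exact = exact,
    rooted = rooted), class = "sir_collapsed")
}

orient_edges <- function(edges_df, rootk, classes, nodes) {
  # BFS orientation away from the root; re-derive each event parent -> child
  adj <- list()
  for (i in seq_len(nrow(edges_df))) {
    adj[[edges_df$parent[i]]] <- c(adj[[edges_df$parent[i]]], i)
    adj[[edges_df$child[i]]] <- c(adj[[edges_df$child[i]]], i)
  }
  out <- edges_df[0, ]
  seen <- rootk
  queue <- rootk
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (i in adj[[x]]) {
      other <- if (edges_df$parent[i] == x) edges_df$child[i]
               else edges_df$parent[i]
      if (other %in% seen) next
      p <- nodes[x, ]; q <- nodes[other, ]
      ci <- which(p != q)
      stp <- sign(q[ci] - p[ci])
      ev <- if (stp < 0) "loss" else if (p[ci] == 0) "innov" else "dup"
      out <- rbind(out, data.frame(parent = x, child = other,
                                   event = sprintf("%s(%s)", ev,
                                                   classes[ci]),
                                   stringsAsFactors = FALSE))
      seen <- c(seen, other)
      queue <- c(queue, other)
    }
  }
  out
}

#' @export
print.sir_collapsed <- function(x, ...) {
  cat(sprintf(paste0("Collapsed species tree: %d nodes (%d predicted), ",
                     "total cost %d (%s%s)\n"),
              nrow(x$nodes), sum(x$nodes$predicted), x$total_cost,
              if (x$exact) "exact" else "heuristic",
              if (x$rooted) ", rooted" else ""))
  invisible(x)
}

#' Predicted intermediate profiles of a collapsed species tree
#'
#' All nodes whose profile matches no observed species, each with its
#' incident edges and the nearest observed species by unit-step edit
#' distance. With `include_path_profiles = TRUE` the prediction set also
#' covers every profile lying on *some* minimal unit-step path of a tree
#' segment (the L1 hyperrectangle between the segment's endpoints), not
#' just the one canonical chain drawn in the tree — any of these states is
#' equally consistent with the parsimonious history.
#'
#' @param collapsed a `sir_collapsed`.
#' @param include_path_profiles also enumerate alternative on-path profiles.
#' @param max_box_profiles cap on enumerated profiles per segment.
#' @return data frame: profile key, incident edge count (0 for alternative
#'   on-path profiles), nearest observed species and its distance. Empty
#'   when nothing is predicted.
#' @export
predict_missing_intermediates <- function(collapsed,
                                          include_path_profiles = FALSE,
                                          max_box_profiles = 5000) {
  pred <- collapsed$nodes$predicted
  ids <- collapsed$nodes$id[pred]
  obs_ids <- collapsed$nodes$id[!pred]
  obs_species <- collapsed$nodes$species[!pred]
  describe <- function(k, p, inc) {
    d <- vapply(obs_ids, function(ok)
      profile_edit_distance(p, collapsed$profiles[ok, ]), numeric(1))
    best <- which.min(d)
    data.frame(id = k, n_incident_edges = inc,
               nearest_species = obs_species[best],
               distance = as.integer(d[best]),
               stringsAsFactors = FALSE)
  }
  out <- lapply(ids, function(k) {
    inc <- sum(collapsed$edges$parent == k | collapsed$edges$child == k)
    describe(k, collapsed$profiles[k, ], inc)
  })
  if (include_path_profiles && nrow(collapsed$segments)) {
    seen <- c(rownames(collapsed$profiles))
    for (i in seq_len(nrow(collapsed$segments))) {
      p <- collapsed$profiles[collapsed$segments$from[i], ]
      q <- collapsed$profiles[collapsed$segments$to[i], ]
      ranges <- lapply(seq_along(p), function(ci)
        seq(min(p[ci], q[ci]), max(p[ci], q[ci])))
      if (prod(lengths(ranges)) > max_box_profiles) next
      box <- as.matrix(expand.grid(ranges))
      colnames(box) <- collapsed$classes
      for (r in seq_len(nrow(box))) {
        key <- profile_key(box[r, ])
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- describe(key, box[r, ], 0L)
      }
    }
  }
  if (!length(out))
    return(data.frame(id = character(0), n_incident_edges = integer(0),
                      nearest_species = character(0),
                      distance = integer(0)))
  do.call(rbind, out)
}

#' Leaf tree over species implied by a collapsed profile tree
#'
#' Attaches each observed species as a pendant leaf to its profile node,
#' suppresses unbranched internals, and returns the unrooted topology for
#' comparison with a reference species tree (e.g. by [robinson_foulds()]).
#'
#' @param collapsed a `sir_collapsed`.
#' @return an [ape::phylo] with one leaf per observed species.
#' @export
species_tree_from_collapse <- function(collapsed) {
  nodek <- collapsed$nodes$id
  idx <- stats::setNames(seq_along(nodek), nodek)
  n_prof <- length(nodek)
  edges <- cbind(idx[collapsed$edges$parent], idx[collapsed$edges$child])
  species <- strsplit(collapsed$nodes$species, ",")
  leaf_names <- character(0)
  nxt <- n_prof
  for (i in seq_len(n_prof)) {
    for (sp in species[[i]]) {
      if (!nzchar(sp)) next
      nxt <- nxt + 1L
      leaf_names[nxt - n_prof] <- sp
      edges <- rbind(edges, c(i, nxt))
    }
  }
  # build newick over this graph: leaves are the species pendants
  nb <- list()
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    nb[[a]] <- c(nb[[a]], edges[i, 2])
    nb[[b]] <- c(nb[[b]], edges[i, 1])
  }
  name_of <- function(v) if (v > n_prof) leaf_names[v - n_prof] else NULL
  rec <- function(v, parent) {
    kids <- setdiff(nb[[as.character(v)]], parent)
    if (!length(kids)) {
      nm <- name_of(v)
      return(if (is.null(nm)) "" else nm)
    }
    parts <- vapply(kids, rec, character(1), parent = v)
    nm <- name_of(v)
    if (!is.null(nm)) parts <- c(parts, nm)   # species on an internal node
    parts <- parts[nzchar(parts)]
    if (length(parts) == 1) return(parts)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  start <- as.integer(names(nb)[1])
  txt <- paste0(rec(start, NULL), ";")
  tr <- ape::read.tree(text = txt)
  ape::collapse.singles(tr)
}
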