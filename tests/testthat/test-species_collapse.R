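make_profiles <- function(counts, classes = NULL) {
  if (is.null(classes)) classes <- letters[seq_len(ncol(counts))]
  dimnames(counts) <- list(paste0("s", seq_len(nrow(counts))), classes)
  structure(counts, class = c("sir_profiles", "matrix"))
}

test_that("class assignment labels clades in manual and automatic modes", {
  # two well-separated clades
  tr <- parse_newick("((u1:0.1,u2:0.1):2,(u3:0.1,u4:0.1):2);")
  auto <- assign_repeat_classes(tr, k = 2)
  expect_equal(auto$k, 2)
  expect_equal(unname(auto$labels[c("u1", "u2")]), c("a", "a"))
  expect_equal(unname(auto$labels[c("u3", "u4")]), c("b", "b"))

  man <- assign_repeat_classes(tr, anchors = list(g1 = c("u1", "u2"),
                                                  g2 = c("u3", "u4")))
  expect_equal(unname(man$labels), unname(auto$labels))

  one <- assign_repeat_classes(tr, k = 1)
  expect_true(all(one$labels == "a"))

  # overlapping anchor clades are rejected, as are non-covering ones
  expect_error(assign_repeat_classes(tr,
    anchors = list(g1 = c("u1", "u3"), g2 = c("u2", "u4"))), "overlap")
  expect_error(assign_repeat_classes(tr, anchors = list(g1 = c("u1", "u2"))),
               "cover")
  expect_error(assign_repeat_classes(tr, k = 2, anchors = list(g = "u1")),
               "exactly one")
})

test_that("k-medoids recovers planted clusters on the repeat tree", {
  set.seed(501)
  for (rep in 1:5) {
    # three planted clusters: tight clades on long stems
    mk <- function(tag, n) paste0("(", paste(sprintf("%s%d:0.05", tag,
                                                     seq_len(n)),
                                             collapse = ","), "):3")
    ns <- sample(3:6, 3, replace = TRUE)
    txt <- sprintf("(%s,%s,%s);", mk("x", ns[1]), mk("y", ns[2]),
                   mk("z", ns[3]))
    tr <- parse_newick(txt)
    cl <- assign_repeat_classes(tr, k = 3)
    truthlab <- substr(tr$tip.label, 1, 1)
    expect_equal(adjusted_rand(cl$labels[tr$tip.label], truthlab), 1)
  }
})

test_that("species profiles count labeled units and keep zero rows", {
  units <- data.frame(
    species = c("sp1", "sp1", "sp2"), protein_id = c("p1", "p1", "p2"),
    ordinal = c(1L, 2L, 1L), start = c(0L, 60L, 0L), end = c(50L, 110L, 50L),
    length = 50L, degenerate = c(FALSE, FALSE, TRUE),
    stringency = c("high", "high", "low"), score = 1,
    sequence = "X", stringsAsFactors = FALSE)
  lab <- structure(list(labels = stats::setNames(c("a", "a", "b"),
                                                 repeat_unit_ids(units)),
                        k = 2), class = "sir_classes")
  P <- build_species_profiles(lab, units, species = c("sp1", "sp2", "sp3"))
  expect_equal(P["sp1", "a"], 2L)
  expect_equal(sum(P["sp2", ]), 0L)       # degenerate excluded by default
  expect_equal(sum(P["sp3", ]), 0L)       # zero profile retained
  P2 <- build_species_profiles(lab, units, species = c("sp1", "sp2"),
                               include_degenerate = TRUE)
  expect_equal(P2["sp2", "b"], 1L)
})

test_that("profile edit distance is the L1 metric and matches BFS search", {
  expect_equal(profile_edit_distance(c(a = 1), c(a = 1)), 0)
  expect_equal(profile_edit_distance(c(a = 2), c(b = 1)), 3)
  expect_error(profile_edit_distance(c(a = -1), c(a = 1)), "negative")

  set.seed(502)
  for (rep in 1:20) {
    u <- stats::setNames(sample(0:3, 3, TRUE), letters[1:3])
    v <- stats::setNames(sample(0:3, 3, TRUE), letters[1:3])
    w <- stats::setNames(sample(0:3, 3, TRUE), letters[1:3])
    d <- profile_edit_distance(u, v)
    expect_equal(d, bfs_edit_distance(u, v))
    expect_equal(d, profile_edit_distance(v, u))
    expect_equal(profile_edit_distance(u, u), 0)
    expect_lte(d, profile_edit_distance(u, w) + profile_edit_distance(w, v))
  }
})

test_that("collapse handles the single-duplication pair exactly", {
  P <- make_profiles(matrix(c(1L, 2L), 2, 1))
  cc <- collapse_to_species_tree(P)
  expect_equal(cc$total_cost, 1)
  expect_equal(nrow(cc$edges), 1)
  expect_match(cc$edges$event, "(dup|loss)\\(a\\)")
  expect_false(any(cc$nodes$predicted))
  expect_equal(nrow(predict_missing_intermediates(cc)), 0)
  expect_error(collapse_to_species_tree(P[1, , drop = FALSE]), ">= 2")
})

test_that("the filozoan-like instance predicts the repeat-class intermediate", {
  P <- matrix(0L, 5, 3,
              dimnames = list(c("ichthyosporean", "filasterean",
                                "choanoflagellate", "basal_metazoan",
                                "bilaterian"), c("a", "b", "c")))
  P["ichthyosporean", "a"] <- 1L
  P["filasterean", "a"] <- 2L
  P["choanoflagellate", ] <- c(1L, 1L, 1L)
  P["basal_metazoan", "b"] <- 1L
  P["bilaterian", "c"] <- 1L
  class(P) <- c("sir_profiles", "matrix")
  cc <- collapse_to_species_tree(P, root_hint = "ichthyosporean")
  expect_true(cc$exact)
  expect_true(cc$rooted)
  expect_equal(cc$total_cost, 6)
  # a predicted ancestor carrying b and c but not a
  bc <- apply(cc$profiles, 1, function(p) p["a"] == 0 && p["b"] >= 1 &&
                p["c"] >= 1)
  expect_true(any(bc & cc$nodes$predicted))
  # a hydra-like observed profile (b:1, c:2) sits one step from it
  pred <- predict_missing_intermediates(cc)
  expect_gt(nrow(pred), 0)
  dmin <- min(apply(cc$profiles[cc$nodes$predicted, , drop = FALSE], 1,
                    function(p) profile_edit_distance(p, c(a = 0, b = 1,
                                                           c = 2))))
  expect_equal(dmin, 1)
  # events replay parent -> child along every edge
  for (i in seq_len(nrow(cc$edges))) {
    p <- cc$profiles[cc$edges$parent[i], ]
    q <- cc$profiles[cc$edges$child[i], ]
    expect_equal(sum(abs(q - p)), 1)
    ev <- sub("\\(.*", "", cc$edges$event[i])
    cls <- sub(".*\\((.)\\)", "\\1", cc$edges$event[i])
    delta <- q[cls] - p[cls]
    expect_equal(unname(delta), if (ev == "loss") -1 else 1)
    if (ev == "innov") expect_equal(unname(p[cls]), 0)
    if (ev == "dup") expect_gte(unname(p[cls]), 1)
  }
})

test_that("exact collapse matches the brute-force Steiner oracle", {
  set.seed(503)
  for (rep in 1:60) {
    nt <- sample(2:5, 1)
    ncl <- sample(1:3, 1)
    P <- make_profiles(matrix(sample(0:3, nt * ncl, TRUE), nt, ncl))
    cc <- collapse_to_species_tree(P)
    expect_true(cc$exact)
    expect_equal(cc$total_cost, brute_steiner_cost(P))
    # bounds: at least the max pairwise distance, at most any star tree
    pairs <- utils::combn(nrow(P), 2)
    dmax <- max(apply(pairs, 2, function(ij)
      profile_edit_distance(P[ij[1], ], P[ij[2], ])))
    star <- min(vapply(seq_len(nrow(P)), function(h)
      sum(apply(P, 1, function(p) profile_edit_distance(p, P[h, ]))),
      numeric(1)))
    expect_gte(cc$total_cost, dmax)
    expect_lte(cc$total_cost, star)
  }
})

test_that("the heuristic engages above the exact-terminal bound", {
  set.seed(504)
  P <- make_profiles(matrix(sample(0:3, 8 * 2, TRUE), 8, 2))
  cc <- collapse_to_species_tree(P, max_exact_terminals = 3)
  expect_false(cc$exact)
  expect_gte(cc$total_cost, brute_steiner_cost(P))
})

test_that("withheld species' true ancestral profile appears among predictions", {
  set.seed(505)
  hits <- replicate(20, {
    cfg <- sim_config_easy(seed = sample.int(1e6, 1))
    tr <- simulate_species_tree(cfg)
    truth <- simulate_repeat_evolution(tr, cfg)
    P <- true_species_profiles(truth)
    nodes <- node_architectures(truth)
    drop <- sample(rownames(P), 1)
    anc <- nodes$architectures[[nodes$parent[[drop]]]]
    anc_prof <- table(factor(anc$class, levels = truth$classes))
    anc_prof <- stats::setNames(as.integer(anc_prof), truth$classes)
    cc <- try(collapse_to_species_tree(P[setdiff(rownames(P), drop), ,
                                         drop = FALSE],
                                       max_exact_terminals = 7),
              silent = TRUE)
    if (inherits(cc, "try-error")) return(NA)
    pred <- predict_missing_intermediates(cc, include_path_profiles = TRUE)
    cand <- unique(c(rownames(cc$profiles), pred$id))
    classes <- colnames(cc$profiles)
    key <- paste(ifelse(classes %in% names(anc_prof),
                        anc_prof[classes], 0L), collapse = ",")
    extra <- setdiff(names(anc_prof)[anc_prof > 0], classes)
    length(extra) == 0 && key %in% cand
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.7)
})
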