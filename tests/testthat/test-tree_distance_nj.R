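test_that("ML distances recover zero, true distances, and the saturation cap", {
  set.seed(401)
  model <- substitution_model("DAYHOFF")
  s <- rand_protein(200)
  aln <- sir_alignment(c("a", "b"), c(s, s))
  d0 <- ml_pairwise_distance(aln, model)
  expect_lt(d0$values["a", "b"], 1e-6)

  # parameter recovery at true distance 0.3 (long sequences)
  est <- replicate(10, {
    root <- stationary_sequence(model, 1000)
    tip <- evolve_string(model, root, 0.3)
    ml_pairwise_distance(sir_alignment(c("a", "b"), c(root, tip)),
                         model)$values["a", "b"]
  })
  expect_true(all(abs(est - 0.3) < 0.05))

  # unrelated sequences hit the cap and are flagged
  r1 <- stationary_sequence(model, 300)
  r2 <- stationary_sequence(model, 300)
  ds <- ml_pairwise_distance(sir_alignment(c("a", "b"), c(r1, r2)), model)
  expect_equal(ds$values["a", "b"], 10)
  expect_true(ds$saturated["a", "b"])

  # gap columns are skipped pairwise; all-gap overlap is an error
  alg <- sir_alignment(c("a", "b"), c("AR-ND", "-RCND"), validate = FALSE)
  expect_silent(ml_pairwise_distance(alg, model))
  bad <- sir_alignment(c("a", "b"), c("AR--", "--ND"), validate = FALSE)
  expect_error(ml_pairwise_distance(bad, model), "a.*b|no shared")
})

test_that("neighbor joining resolves three taxa by the exact formulas", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(distance_matrix(c("A", "B", "C"), D))
  pl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(pl[c("A", "B", "C")], c(A = 1, B = 1, C = 2))
  expect_error(neighbor_joining(distance_matrix("A", matrix(0, 1, 1))),
               ">= 3")
})

test_that("neighbor joining recovers additive matrices exactly", {
  true <- parse_newick("((A:1,B:2):1,C:3,D:4);")
  D <- ape::cophenetic.phylo(true)
  est <- neighbor_joining(D)
  expect_equal(robinson_foulds(est, true), 0)
  expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)

  set.seed(402)
  for (rep in 1:25) {
    tr <- rand_tree(sample(6:10, 1), 0.1, 2)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(robinson_foulds(est, tr), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] -
                        D)), 1e-9)
    # cross-check against the reference implementation
    ref <- ape::nj(D)
    expect_equal(robinson_foulds(est, ref), 0)
  }
})

test_that("all-equal distances give a deterministic tie-broken topology", {
  labs <- c("d", "b", "a", "c", "e")
  D <- matrix(1, 5, 5, dimnames = list(labs, labs))
  diag(D) <- 0
  t1 <- neighbor_joining(distance_matrix(labs, D))
  t2 <- neighbor_joining(distance_matrix(labs, D))
  expect_identical(write_newick(t1), write_newick(t2))
  # first join is the lexicographically smallest pair (a, b)
  expect_match(write_newick(t1), "\\((a|b):[0-9.]+,(a|b):")
})
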