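test_that("two-leaf likelihoods match closed forms", {
  model <- substitution_model("WAG")
  # zero branch, single shared residue: lnL = log pi_A
  tr <- parse_newick("(a:0,b:0);")
  aln <- sir_alignment(c("a", "b"), c("A", "A"))
  expect_equal(log_likelihood(tr, aln, model),
               log(model$frequencies[["A"]]), tolerance = 1e-10)
  # positive branch: lnL = log(pi_x P_xy(t)) via independent expm
  t <- 0.37
  tr2 <- parse_newick(sprintf("(a:%g,b:%g);", t / 2, t / 2))
  aln2 <- sir_alignment(c("a", "b"), c("A", "R"))
  P <- as.matrix(Matrix::expm(model$Q * t))
  expect_equal(log_likelihood(tr2, aln2, model),
               log(model$frequencies[["A"]] * P[1, 2]), tolerance = 1e-8)
})

test_that("pruning equals exhaustive state summation on small trees", {
  set.seed(411)
  for (rep in 1:4) {
    ntip <- sample(4:5, 1)
    tr <- rand_tree(ntip, 0.05, 0.6)
    model <- if (rep %% 2) substitution_model("WAG")
             else substitution_model("DAYHOFF", alpha = 0.7, n_categories = 2)
    aln <- simulate_alignment(tr, model, 5)
    expect_equal(log_likelihood(tr, aln, model),
                 brute_loglik(tr, aln, model), tolerance = 1e-8)
  }
})

test_that("gaps are treated as missing data", {
  model <- substitution_model("WAG")
  tr <- rand_tree(4, 0.1, 0.4)
  aln <- sir_alignment(paste0("t", 1:4), c("AR", "A-", "AX", "AR"))
  # column 2 with gaps/X contributes like a smaller leaf set
  expect_equal(log_likelihood(tr, aln, model),
               brute_loglik(tr, aln, model), tolerance = 1e-8)
})

test_that("pruning agrees with the reference implementation with gamma", {
  set.seed(412)
  suppressPackageStartupMessages(requireNamespace("phangorn"))
  for (rep in 1:4) {
    tr <- rand_tree(5, 0.05, 0.8)
    model <- if (rep == 1) substitution_model("DAYHOFF")
             else substitution_model(c("WAG", "DAYHOFF")[rep %% 2 + 1],
                                     alpha = c(0.4, 1, 3)[rep - 1],
                                     n_categories = 4)
    aln <- simulate_alignment(tr, model, 60)
    pd <- phangorn::phyDat(alignment_matrix(aln), type = "AA")
    fit <- phangorn::pml(tr, pd,
                         model = if (model$name == "WAG") "WAG" else "Dayhoff",
                         k = model$k,
                         shape = if (is.null(model$alpha)) 1 else model$alpha)
    expect_equal(log_likelihood(tr, aln, model), fit$logLik,
                 tolerance = 1e-6)
  }
  # label mismatch reports the asymmetric difference
  tr <- rand_tree(4)
  aln <- sir_alignment(c("t1", "t2", "t3", "zz"), rep("ARN", 4))
  expect_error(log_likelihood(tr, aln, substitution_model("WAG")),
               "zz.*t4|t4.*zz")
})

test_that("branch-length optimization never decreases the likelihood", {
  set.seed(413)
  model <- substitution_model("WAG")
  tr <- rand_tree(5, 0.1, 0.5)
  aln <- simulate_alignment(tr, model, 80)
  start <- tr
  start$edge.length <- rep(0.25, nrow(start$edge))
  lnl0 <- log_likelihood(start, aln, model)
  fit <- optimize_branch_lengths(start, aln, model)
  expect_gte(fit$logLik, lnl0)
  expect_equal(fit$logLik, log_likelihood(fit$tree, aln, model),
               tolerance = 1e-9)
})
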