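test_that("identical sequences align without gaps at their self-score", {
  r <- global_pairwise_align("MKV", "MKV")
  expect_equal(r$alignment$rows, c("MKV", "MKV"))
  sub <- score_matrix("BLOSUM62")
  expect_equal(r$score, sub["M", "M"] + sub["K", "K"] + sub["V", "V"])
  expect_error(global_pairwise_align("A", ""), "empty")
})

test_that("alignment scores match exhaustive enumeration on short pairs", {
  set.seed(301)
  sub <- score_matrix("BLOSUM62")
  for (rep in 1:50) {
    a <- rand_protein(sample(1:6, 1))
    b <- rand_protein(sample(1:6, 1))
    mine <- global_pairwise_align(a, b)
    brute <- brute_align_score(a, b, sub, 10, 0.5)
    expect_equal(mine$score, brute)
  }
})

test_that("alignment scores match Biostrings and degap to the inputs", {
  set.seed(302)
  sub <- score_matrix("BLOSUM62")
  for (rep in 1:25) {
    a <- rand_protein(sample(5:40, 1))
    b <- rand_protein(sample(5:40, 1))
    mine <- global_pairwise_align(a, b)
    ora <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sub, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(mine$score, Biostrings::score(ora))
    expect_equal(alignment_degap(mine$alignment, 1), a)
    expect_equal(alignment_degap(mine$alignment, 2), b)
    # determinism
    again <- global_pairwise_align(a, b)
    expect_identical(mine$alignment$rows, again$alignment$rows)
  }
})

test_that("percent identity counts columns per mode and is symmetric", {
  al <- sir_alignment(c("x", "y"), c("AAAA", "AAAT"))
  expect_equal(percent_identity(al), 75)
  ident <- sir_alignment(c("x", "y"), c(rand_protein(50), ""), validate = FALSE)
  ident$rows[2] <- ident$rows[1]
  expect_equal(percent_identity(ident), 100)

  # terminal gaps counted only under all_columns
  al2 <- sir_alignment(c("x", "y"), c("--AAAA", "TTAAAA"))
  expect_equal(percent_identity(al2, "exclude_terminal_gaps"), 100)
  expect_equal(percent_identity(al2, "all_columns"), 100 * 4 / 6)

  # gap-gap columns never counted
  al3 <- sir_alignment(c("x", "y"), c("A-A", "A-T"), validate = FALSE)
  expect_equal(percent_identity(al3, "all_columns"), 50)

  set.seed(303)
  for (rep in 1:10) {
    r <- global_pairwise_align(rand_protein(30), rand_protein(25))$alignment
    sw <- sir_alignment(rev(r$ids), rev(r$rows))
    expect_equal(percent_identity(r), percent_identity(sw))
  }
  expect_error(percent_identity(sir_alignment(c("a","b","c"),
                                              c("A","A","A"))), "2 rows")
})

test_that("progressive alignment keeps substitution-only inputs gap-free", {
  msa <- progressive_msa(stats::setNames(c("MKV", "MKV", "MKV"),
                                         c("x", "y", "z")))
  expect_equal(alignment_ncol(msa), 3)
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))

  set.seed(304)
  for (rep in 1:10) {
    base <- rand_protein(50)
    vars <- vapply(1:6, function(i) mutate_protein(base, sample(3:10, 1)),
                   character(1))
    msa <- progressive_msa(stats::setNames(vars, paste0("v", 1:6)))
    expect_equal(alignment_ncol(msa), 50)
    expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
    for (i in 1:6) expect_equal(alignment_degap(msa, i), vars[[i]])
  }
  expect_error(progressive_msa(c(one = "MKV")), "at least 2")
})

test_that("progressive alignment beats naive stacking by sum-of-pairs", {
  set.seed(305)
  wins <- replicate(20, {
    base <- rand_protein(40)
    seqs <- vapply(1:4, function(i) {
      v <- mutate_protein(base, 6)
      if (runif(1) < 0.5) v <- paste0(v, rand_protein(sample(1:6, 1)))
      v
    }, character(1))
    msa <- progressive_msa(stats::setNames(seqs, paste0("s", 1:4)))
    width <- max(nchar(seqs))
    naive <- sir_alignment(paste0("s", 1:4),
                           vapply(seqs, function(s)
                             paste0(s, strrep("-", width - nchar(s))),
                             character(1)), validate = FALSE)
    sum_of_pairs_score(msa) >= sum_of_pairs_score(naive)
  })
  expect_true(all(wins))
})

test_that("projected pairwise scores never exceed the optimal pairwise score", {
  set.seed(306)
  for (rep in 1:5) {
    base <- rand_protein(30)
    seqs <- vapply(1:4, function(i) mutate_protein(base, sample(2:8, 1)),
                   character(1))
    names(seqs) <- paste0("s", 1:4)
    msa <- progressive_msa(seqs)
    m <- alignment_matrix(msa)
    sub <- score_matrix("BLOSUM62")
    for (i in 1:3) for (j in (i + 1):4) {
      keep <- !(m[i, ] == "-" & m[j, ] == "-")
      proj <- sir_alignment(c("a", "b"),
                            c(paste(m[i, keep], collapse = ""),
                              paste(m[j, keep], collapse = "")),
                            validate = FALSE)
      expect_lte(sum_of_pairs_score(proj),
                 global_pairwise_align(seqs[[i]], seqs[[j]])$score + 1e-9)
    }
  }
})

test_that("aligned FASTA round-trips through the import adapter", {
  f <- withr::local_tempfile()
  al <- sir_alignment(c("u1", "u2"), c("MK-V", "MKAV"))
  write_alignment_fasta(al, f)
  back <- read_alignment_fasta(f)
  expect_equal(back$ids, al$ids)
  expect_equal(back$rows, al$rows)
})
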