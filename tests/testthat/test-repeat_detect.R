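test_that("self dot matrix marks the full diagonal and is symmetric", {
  set.seed(201)
  s <- rand_protein(120)
  dm <- compute_dot_matrix(s, s, window = 11, min_score_fraction = 1.0)
  on_diag <- dm$marks[dm$marks[, 1] == dm$marks[, 2], , drop = FALSE]
  expect_equal(nrow(on_diag), 120 - 10)
  flipped <- dm$marks[, c(2, 1)]
  expect_setequal(paste(dm$marks[, 1], dm$marks[, 2]),
                  paste(flipped[, 2], flipped[, 1]))

  expect_error(compute_dot_matrix(s, s, window = 10), "odd")
  expect_error(compute_dot_matrix("MKV", s, window = 11), "length")
  expect_error(compute_dot_matrix(s, s, matrix_name = "NOPE"), "unknown")
})

test_that("tandem copies show an off-diagonal run at the repeat offset", {
  set.seed(202)
  B <- rand_protein(50)
  S <- rand_protein(30, pool = c("G", "P", "Q", "E"))
  seq <- paste0(B, S, B)
  dm <- compute_dot_matrix(seq, seq, window = 11, min_score_fraction = 1.0)
  off <- dm$marks[dm$marks[, 1] - dm$marks[, 2] == 80, , drop = FALSE]
  expect_gte(nrow(off), 40)
})

test_that("lowering the stringency threshold never removes marks", {
  set.seed(203)
  a <- rand_protein(80)
  b <- mutate_protein(a, 20)
  hi <- compute_dot_matrix(a, b, min_score_fraction = 0.6)
  lo <- compute_dot_matrix(a, b, min_score_fraction = 0.3)
  hik <- paste(hi$marks[, 1], hi$marks[, 2])
  lok <- paste(lo$marks[, 1], lo$marks[, 2])
  expect_true(all(hik %in% lok))
})

test_that("diverged planted copies mark most true repeat diagonal centers", {
  set.seed(204)
  hit_frac <- replicate(10, {
    dom <- rand_protein(50)
    copy <- mutate_protein(dom, 8)            # ~85% identity
    linker <- planted_linker(dom, c(10, 90))
    linker <- paste0(substr(linker, 1, 90), copy,
                     substr(linker, 141, nchar(linker)))
    dm <- compute_dot_matrix(linker, dom, window = 11,
                             min_score_fraction = 0.5)
    centers <- dm$marks[dm$marks[, 1] - dm$marks[, 2] == 90, 1]
    valid <- 95:135                           # window-center range of copy 2
    length(intersect(centers, valid)) / length(valid)
  })
  expect_gte(mean(hit_frac >= 0.9), 0.9)
})

test_that("anchored linker extraction recovers planted coordinates", {
  set.seed(205)
  ers <- rand_protein(60)
  prs <- rand_protein(60)
  L <- rand_protein(150)
  prot <- paste0(ers, L, prs)
  lk <- extract_linker(prot, ers, prs)
  expect_equal(lk$start, 60)
  expect_equal(lk$end, 210)
  expect_equal(lk$sequence, L)

  # 20% substitution noise in the anchors: within +/- 5 residues
  for (rep in 1:10) {
    ersm <- mutate_protein(ers, 12)
    prsm <- mutate_protein(prs, 12)
    lk2 <- extract_linker(paste0(ersm, L, prsm), ers, prs)
    expect_lte(abs(lk2$start - 60), 5)
    expect_lte(abs(lk2$end - 210), 5)
  }

  expect_error(extract_linker(paste0(ers, L), ers, prs),
               "anchor not found: PRS")
  expect_error(extract_linker(paste0(prs, L, ers), ers, prs),
               "out of order")
  expect_error(extract_linker(prot, "MKV", prs), ">= 30")
})

test_that("boundary calling is exact on exact copies and robust at 85% identity", {
  set.seed(206)
  dom <- rand_protein(50)
  linker <- planted_linker(dom, c(10, 90))
  u <- call_repeat_boundaries(linker, dom)
  expect_equal(u$start, c(10, 90))
  expect_equal(u$end, c(60, 140))
  expect_equal(u$ordinal, c(1, 2))
  expect_equal(u$sequence, c(dom, dom))

  # exactness holds for any window <= domain length
  for (w in c(3, 7, 21, 49)) {
    uw <- call_repeat_boundaries(linker, dom, window = w)
    expect_equal(uw$start, c(10, 90))
  }

  # planted diverged copies: starts within +/-3 in >= 95% of replicates
  ok <- replicate(30, {
    dom <- rand_protein(50)
    linker <- planted_linker(dom, c(10, 90), identity = 0.85)
    u <- call_repeat_boundaries(linker, dom)
    nrow(u) == 2 && all(abs(sort(u$start) - c(10, 90)) <= 3)
  })
  expect_gte(mean(ok), 0.95)

  # negative control: unrelated linker yields no units at high stringency
  fp <- replicate(20, {
    nrow(call_repeat_boundaries(rand_protein(200), rand_protein(50)))
  })
  expect_lte(mean(fp > 0), 0.1)

  # degenerate inputs
  expect_equal(nrow(call_repeat_boundaries("", dom)), 0)
  expect_warning(out <- call_repeat_boundaries(rand_protein(30), dom),
                 "exceeds")
  expect_equal(nrow(out), 0)
  expect_error(call_repeat_boundaries(linker, rand_protein(40)),
               "exactly domain_length")
})

test_that("two-stringency detection flags only weakly conserved units", {
  set.seed(207)
  dom <- rand_protein(50)
  faded <- mutate_protein(dom, 30)            # ~40% identity
  linker <- planted_linker(dom, c(10, 90))
  linker <- paste0(substr(linker, 1, 90), faded,
                   substr(linker, 141, nchar(linker)))
  u <- detect_degenerate_repeats(linker, dom)
  expect_true(any(!u$degenerate))
  exact_unit <- u[u$start == 10, ]
  expect_false(exact_unit$degenerate)
  if (any(u$start == 90)) {
    expect_true(u$degenerate[u$start == 90])
    expect_equal(u$stringency[u$start == 90], "low")
  }

  # exact copies are never degenerate
  u2 <- detect_degenerate_repeats(planted_linker(dom, c(10, 90)), dom)
  expect_false(any(u2$degenerate))
  # non-degenerate units do not overlap and are ordinal-sorted
  nd <- u2[!u2$degenerate, ]
  expect_true(all(diff(nd$start) >= 50))
  expect_equal(nd$ordinal, order(nd$start))

  expect_error(detect_degenerate_repeats(linker, dom,
    high_cfg = list(window = 11, matrix_name = "PAM250",
                    min_score_fraction = 0.3),
    low_cfg = list(window = 11, matrix_name = "PAM250",
                   min_score_fraction = 0.5)), "below")
})
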