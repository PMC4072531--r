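test_that("species trees pass through, reproduce, and match birth expectations", {
  nwk <- "((s1:1,s2:1):1,(s3:1,s4:1):1);"
  cfg <- sim_config(species_tree = nwk)
  tr <- simulate_species_tree(cfg)
  expect_equal(write_newick(tr), write_newick(parse_newick(nwk)))

  set.seed(601)
  cfg2 <- sim_config(n_species = 4, speciation = 1, extinction = 0)
  t1 <- simulate_species_tree(cfg2)
  expect_equal(length(t1$tip.label), 4)
  set.seed(601)
  t2 <- simulate_species_tree(cfg2)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-6))

  # crown birth process: E[N(T)] = 2 e^T for pure birth from two lineages
  set.seed(602)
  T0 <- 0.7
  cfg3 <- sim_config(speciation = 1, extinction = 0, crown_age = T0)
  n <- replicate(500, length(simulate_species_tree(cfg3)$tip.label))
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - 2 * exp(T0)), 3 * se)
})

test_that("repeat birth-death respects degenerate rates and expectations", {
  tr <- parse_newick("((s1:1,s2:1):1,(s3:1,s4:1):1);")

  # no rates: architectures equal the root everywhere
  cfg0 <- sim_config(species_tree = write_newick(tr), lambda_dup = 0,
                     lambda_loss = 0, lambda_innov = 0,
                     root_architecture = c("a", "b"))
  truth0 <- simulate_repeat_evolution(tr, cfg0)
  for (sp in names(truth0$architectures))
    expect_equal(truth0$architectures[[sp]]$class, c("a", "b"))
  expect_equal(nrow(truth0$events), 0)

  # no loss: counts never fall below the root count
  set.seed(603)
  for (s in 1:10) {
    cfgn <- sim_config(seed = s, species_tree = write_newick(tr),
                       lambda_dup = 0.4, lambda_loss = 0,
                       lambda_innov = 0.1)
    tn <- simulate_repeat_evolution(tr, cfgn)
    expect_true(all(vapply(tn$architectures, nrow, integer(1)) >= 1))
  }

  # linear birth-death expectation: E[N] = n0 exp((dup+innov-loss) * depth)
  set.seed(604)
  two <- parse_newick("(s1:1,s2:1);")
  lam <- 0.5; mu <- 0.2; nu <- 0.1
  counts <- vapply(1:500, function(s) {
    cfg <- sim_config(seed = s, species_tree = write_newick(two),
                      lambda_dup = lam, lambda_loss = mu, lambda_innov = nu,
                      root_architecture = c("a", "a"))
    tt <- simulate_repeat_evolution(two, cfg)
    nrow(tt$architectures$s1)
  }, numeric(1))
  expected <- 2 * exp((lam + nu - mu) * 1)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("event-log replay reproduces every leaf architecture", {
  set.seed(605)
  for (s in 1:5) {
    cfg <- sim_config_easy(seed = sample.int(1e6, 1))
    tr <- simulate_species_tree(cfg)
    truth <- simulate_repeat_evolution(tr, cfg)
    rep <- replay_event_log(truth)
    for (sp in names(truth$architectures)) {
      expect_identical(rep[[sp]]$unit_id, truth$architectures[[sp]]$unit_id)
      expect_identical(rep[[sp]]$class, truth$architectures[[sp]]$class)
    }
  }
})

test_that("sequence evolution honors zero rates and the rate-tier ordering", {
  tr <- parse_newick("((s1:1,s2:1):1,(s3:1,s4:1):1);")
  model <- substitution_model("WAG")

  cfg0 <- sim_config(species_tree = write_newick(tr), lambda_dup = 0,
                     lambda_loss = 0, lambda_innov = 0, subs_scale = 0,
                     root_architecture = "a")
  truth0 <- simulate_repeat_evolution(tr, cfg0)
  sd0 <- evolve_sequences(truth0, model, cfg0)
  expect_equal(length(unique(sd0$units$sequence)), 1)
  expect_equal(sd0$units$sequence[1], unname(sd0$root_domains["a"]))

  # tier ordering: flank identity > domain identity > spacer identity
  set.seed(606)
  ords <- replicate(8, {
    cfg <- sim_config(seed = sample.int(1e6, 1),
                      species_tree = write_newick(tr),
                      lambda_dup = 0, lambda_loss = 0, lambda_innov = 0,
                      root_architecture = c("a", "a"))
    truth <- simulate_repeat_evolution(tr, cfg)
    sd <- evolve_sequences(truth, model, cfg)
    pid <- function(x, y) {
      a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
      100 * mean(a == b)
    }
    pr <- stats::setNames(sd$proteins$residues, sd$proteins$id)
    u <- sd$units
    d1 <- u[u$species == "s1", ]
    d3 <- u[u$species == "s3", ]
    dom_id <- pid(d1$sequence[1], d3$sequence[1])
    flank_id <- pid(substr(pr["s1"], 1, 60), substr(pr["s3"], 1, 60))
    # spacer between unit 1 and unit 2 (coordinates from the truth table)
    spc <- function(sp) {
      uu <- u[u$species == sp, ]
      substr(pr[sp], uu$end[1] + 1, uu$start[2])
    }
    s1sp <- spc("s1"); s3sp <- spc("s3")
    spacer_id <- if (nchar(s1sp) == nchar(s3sp)) pid(s1sp, s3sp) else 0
    c(flank_id, dom_id, spacer_id)
  })
  means <- rowMeans(ords)
  expect_gt(means[1], means[2])
  expect_gt(means[2], means[3])

  # class-founding burst increases between-class divergence
  set.seed(607)
  div_at_burst <- function(bf) {
    vals <- c()
    for (s in 1:6) {
      cfg <- sim_config(seed = s, species_tree = write_newick(tr),
                        lambda_dup = 0, lambda_loss = 0, lambda_innov = 0.4,
                        burst_factor = bf, root_architecture = "a")
      truth <- simulate_repeat_evolution(tr, cfg)
      if (length(truth$classes) < 2) next
      sd <- evolve_sequences(truth, model, cfg)
      u <- sd$units
      for (sp in unique(u$species)) {
        us <- u[u$species == sp, ]
        if (length(unique(us$class)) < 2) next
        pairs <- utils::combn(nrow(us), 2)
        for (pi in seq_len(ncol(pairs))) {
          i <- pairs[1, pi]; j <- pairs[2, pi]
          if (us$class[i] == us$class[j]) next
          a <- strsplit(us$sequence[i], "")[[1]]
          b <- strsplit(us$sequence[j], "")[[1]]
          vals <- c(vals, mean(a != b))
        }
      }
    }
    mean(vals)
  }
  expect_gt(div_at_burst(5), div_at_burst(0.2))
})

test_that("emitted datasets are slice-exact, complete and deterministic", {
  cfg <- sim_config_easy(seed = 42)
  tr <- simulate_species_tree(cfg)
  truth <- simulate_repeat_evolution(tr, cfg)
  model <- substitution_model("WAG")
  sd <- evolve_sequences(truth, model, cfg)
  out1 <- withr::local_tempdir()
  emit_dataset(out1, sd)
  expect_setequal(list.files(out1),
                  c("proteins.faa", "species_tree.nwk", "truth_units.tsv",
                    "truth_events.tsv"))
  units <- utils::read.delim(file.path(out1, "truth_units.tsv"))
  expect_equal(nrow(units),
               sum(vapply(truth$architectures, nrow, integer(1))))
  prot <- read_fasta(file.path(out1, "proteins.faa"), "protein")
  for (i in seq_len(nrow(units))) {
    s <- prot$residues[prot$id == units$species[i]]
    expect_equal(substr(s, units$start[i] + 1, units$end[i]),
                 units$sequence[i])
  }
  # byte-identical rerun
  out2 <- withr::local_tempdir()
  sd2 <- evolve_sequences(simulate_repeat_evolution(tr, cfg), model, cfg)
  emit_dataset(out2, sd2)
  for (f in list.files(out1))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})
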