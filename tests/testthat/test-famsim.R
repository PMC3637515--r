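test_that("sampled trees have the right shape and labels", {
  tr <- sample_tree(4, rng_seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(tree_splits(tr), 1)          # one internal edge, unrooted
  expect_equal(sort(tr$tip.label), paste0("t", 1:4))
  tr2 <- sample_tree(9, rng_seed = 2)
  expect_equal(length(tr2$tip.label), 9)
  expect_false(anyDuplicated(tr2$tip.label) > 0)
  expect_true(all(tr2$edge.length > 0))
  # determinism
  expect_equal(to_newick(sample_tree(7, rng_seed = 5)),
               to_newick(sample_tree(7, rng_seed = 5)))
})

test_that("4-leaf Yule topologies are equiprobable", {
  counts <- table(vapply(1:600, function(i) {
    tree_splits(sample_tree(4, rng_seed = i))
  }, character(1)))
  expect_length(counts, 3)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("zero rates copy the root to every leaf", {
  tr <- sample_tree(5, rng_seed = 3)
  tr$edge.length[] <- 0
  fam <- evolve_sequences(tr, sim_config(n_leaves = 5, root_length = 40,
                                         indel_rate = 0, flank_length = 0),
                          rng_seed = 4)
  res <- vapply(fam$records, `[[`, "", "residues")
  expect_equal(length(unique(res)), 1L)
  expect_equal(fam$mean_identity, 1)
})

test_that("realized identity matches the closed form", {
  # two leaves joined by total path length t, no indels
  for (t in c(0.3, 0.65)) {
    tr <- from_newick(sprintf("(a:%f,b:%f,(c:5,d:5):5);", t / 2, t / 2))
    idents <- vapply(1:60, function(i) {
      fam <- evolve_sequences(tr, sim_config(n_leaves = 4, root_length = 200,
                                             indel_rate = 0,
                                             flank_length = 0),
                              rng_seed = i)
      a <- fam$records[[match("a", vapply(fam$records, `[[`, "", "id"))]]
      b <- fam$records[[match("b", vapply(fam$records, `[[`, "", "id"))]]
      mean(strsplit(a$residues, "")[[1]] == strsplit(b$residues, "")[[1]])
    }, numeric(1))
    expect_lt(abs(mean(idents) - expected_pairwise_identity(t)), 0.02)
  }
})

test_that("identity decreases with path length", {
  ts <- c(0.2, 0.6, 1.2, 2.5)
  means <- vapply(seq_along(ts), function(k) {
    tr <- from_newick(sprintf("(a:%f,b:%f,(c:1,d:1):1);",
                              ts[k] / 2, ts[k] / 2))
    mean(vapply(1:25, function(i) {
      fam <- evolve_sequences(tr, sim_config(n_leaves = 4, root_length = 150,
                                             indel_rate = 0,
                                             flank_length = 0),
                              rng_seed = k * 100 + i)
      a <- fam$records[[match("a", vapply(fam$records, `[[`, "", "id"))]]
      b <- fam$records[[match("b", vapply(fam$records, `[[`, "", "id"))]]
      mean(strsplit(a$residues, "")[[1]] == strsplit(b$residues, "")[[1]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("expected_identity targeting hits the requested regime", {
  fam <- simulate_family(sim_config(n_leaves = 10, root_length = 200,
                                    expected_identity = 0.55, rng_seed = 6))
  expect_lt(abs(fam$mean_identity - 0.55), 0.08)
  fam30 <- simulate_family(sim_config(n_leaves = 10, root_length = 200,
                                      expected_identity = 0.30, rng_seed = 7))
  expect_lt(abs(fam30$mean_identity - 0.30), 0.08)
  expect_lt(fam30$mean_identity, fam$mean_identity)
})

test_that("boundaries, flanks and determinism are coherent", {
  cfg <- sim_config(n_leaves = 6, root_length = 50, flank_length = 20,
                    rng_seed = 44)
  fam <- simulate_family(cfg)
  fam2 <- simulate_family(cfg)
  expect_identical(vapply(fam$records, `[[`, "", "residues"),
                   vapply(fam2$records, `[[`, "", "residues"))
  expect_equal(to_newick(fam$true_tree), to_newick(fam2$true_tree))
  expect_true(all(fam$boundaries$start == 20))
  doms <- extract_domains(fam$records, fam$boundaries)
  expect_equal(vapply(doms, `[[`, "", "residues"), fam$domains)
  expect_setequal(fam$boundaries$id, fam$true_tree$tip.label)
})

test_that("leaf length is stable when insertion and deletion rates balance", {
  tr <- sample_tree(6, branch_mean = 0.5, rng_seed = 12)
  lens <- unlist(lapply(1:20, function(i) {
    fam <- evolve_sequences(tr, sim_config(n_leaves = 6, root_length = 100,
                                           indel_rate = 0.05,
                                           flank_length = 0),
                            rng_seed = 500 + i)
    vapply(fam$records, function(r) nchar(r$residues), numeric(1))
  }))
  expect_lt(abs(mean(lens) - 100), 5)
})

test_that("family artifacts are written and re-readable", {
  fam <- simulate_family(sim_config(n_leaves = 5, root_length = 40,
                                    rng_seed = 3))
  d <- withr::local_tempdir()
  write_family(fam, d)
  recs <- read_fasta(file.path(d, "leaves.fasta"))
  expect_length(recs, 5)
  tt <- from_newick(path = file.path(d, "true_tree.nwk"))
  expect_equal(rf_distance(tt, fam$true_tree), 0)
  cfg <- jsonlite::read_json(file.path(d, "config.json"))
  expect_equal(cfg$n_leaves, 5)
  expect_equal(cfg$mean_identity, fam$mean_identity)
})
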