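test_that("NJ resolves an additive 4-taxon matrix with exact lengths", {
  # tree ((A:1,B:2):1.5,(C:3,D:4)); pairwise path sums below
  dm <- matrix(c(0, 3, 5.5, 6.5,
                 3, 0, 6.5, 7.5,
                 5.5, 6.5, 0, 7,
                 6.5, 7.5, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  expect_equal(rf_distance(tr, from_newick("((A,B),(C,D));")), 0)
  # recovered path lengths reproduce the input exactly
  expect_equal(stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], dm,
               tolerance = 1e-9)
})

test_that("identical rows form a zero-length cherry", {
  dm <- matrix(c(0, 0, 8, 8,
                 0, 0, 8, 8,
                 8, 8, 0, 2,
                 8, 8, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(dm)
  expect_equal(rf_distance(tr, from_newick("((a,b),(c,d));")), 0)
  co <- stats::cophenetic(tr)
  expect_equal(unname(co["a", "b"]), 0)
})

test_that("NJ is consistent on random additive matrices", {
  for (seed in 1:20) {
    n <- sample(6:12, 1)
    case <- random_additive_case(n, seed)
    tr <- nj_tree(case$dm)
    expect_equal(rf_distance(tr, case$tree), 0)
    expect_equal(stats::cophenetic(tr)[rownames(case$dm), rownames(case$dm)],
                 case$dm, tolerance = 1e-6)
    # cross-check against the reference NJ implementation
    expect_equal(rf_distance(ape::nj(case$dm), tr), 0)
  }
})

test_that("5-taxon NJ matches exhaustive minimum-evolution search", {
  labs <- paste0("t", 1:5)
  for (seed in 1:10) {
    case <- random_additive_case(5, seed + 100)
    dm <- case$dm[labs, labs]
    fits <- lapply(five_taxon_topologies(labs), ols_tree_fit, dm = dm)
    sse <- vapply(fits, `[[`, numeric(1), "sse")
    tot <- vapply(fits, `[[`, numeric(1), "total")
    best <- five_taxon_topologies(labs)[which.min(tot + 1e6 * (sse > 1e-6))]
    tr <- nj_tree(dm)
    expect_equal(rf_distance(tr, ape::read.tree(text = best)), 0)
  }
})

test_that("branch lengths are clamped non-negative on noisy matrices", {
  set.seed(17)
  for (k in 1:10) {
    case <- random_additive_case(7, k + 300)
    noisy <- case$dm + matrix(runif(49, 0, 0.4), 7, 7)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    tr <- nj_tree(noisy)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("NJ is equivariant under leaf relabeling", {
  case <- random_additive_case(8, 55)
  tr1 <- nj_tree(case$dm)
  perm <- sample(8)
  tr2 <- nj_tree(case$dm[perm, perm])
  expect_equal(rf_distance(tr1, tr2), 0)
})

test_that("Newick round trips preserve topology, lengths and labels", {
  txt <- "(A:1,B:2,(C:3,D:4):5);"
  tr <- from_newick(txt)
  expect_equal(to_newick(tr), txt)

  # unlabeled internal nodes and support labels are accepted
  tr2 <- from_newick("((A:1,B:1)90:2,(C:1,D:1):2,E:3);")
  expect_equal(tr2$node.label[2], "90")

  big <- sample_tree(200, rng_seed = 9)
  rt <- from_newick(to_newick(big))
  expect_equal(rf_distance(rt, big), 0)
  expect_equal(sort(rt$tip.label), sort(big$tip.label))
  co1 <- stats::cophenetic(big)
  expect_equal(stats::cophenetic(rt)[rownames(co1), colnames(co1)], co1,
               tolerance = 1e-8)
  expect_error(from_newick("((A,B);"), "")
})

test_that("Robinson-Foulds distance matches independent bipartition counts", {
  expect_equal(rf_distance(from_newick("((A,B),(C,D));"),
                           from_newick("((A,B),(C,D));")), 0)
  expect_equal(rf_distance(from_newick("((A,B),(C,D));"),
                           from_newick("((A,C),(B,D));")), 2)
  for (seed in 1:10) {
    n <- sample(6:15, 1)
    t1 <- sample_tree(n, rng_seed = seed * 2)
    t2 <- sample_tree(n, rng_seed = seed * 2 + 1)
    got <- rf_distance(t1, t2)
    # oracle: symmetric difference of prop.part-derived split sets
    c1 <- names(oracle_split_counts(list(t1)))
    c2 <- names(oracle_split_counts(list(t2)))
    expect_equal(got, length(setdiff(c1, c2)) + length(setdiff(c2, c1)))
    # cross-check with phangorn
    expect_equal(got, phangorn::RF.dist(t1, t2))
  }
  expect_error(rf_distance(from_newick("((A,B),(C,D));"),
                           from_newick("((A,B),(C,E));")),
               "leaf set")
})

test_that("N < 3 and malformed matrices are rejected", {
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
  m <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_tree(m), "symmetric")
})
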