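test_that("single-sequence profile prefers the seed residue per column", {
  set.seed(3)
  res <- random_residues(30)
  p <- single_seq_pssm(res)
  argmax <- AA20[apply(p$scores, 1, which.max)]
  expect_equal(argmax, strsplit(res, "")[[1]])
  expect_equal(p$length, 30L)
  expect_equal(p$seed_residues, res)
})

test_that("identical database copies collapse to the single-copy profile", {
  set.seed(77)
  res <- random_residues(30)
  seed <- seq_record("s", res)
  copies <- lapply(1:10, function(i) seq_record(paste0("c", i), res))
  p1 <- build_pssm(seed, list(seed), evalue_threshold = 1e-3,
                   iterations = 1, n_decoys = 30, rng_seed = 1)
  p10 <- build_pssm(seed, copies, evalue_threshold = 1e-3,
                    iterations = 1, n_decoys = 30, rng_seed = 1)
  # position-based weighting normalizes duplicates: every column's top
  # score is for the seed residue and equals the single-copy value
  expect_equal(AA20[apply(p10$scores, 1, which.max)],
               strsplit(res, "")[[1]])
  expect_equal(p10$scores, p1$scores, tolerance = 1e-12)
})

test_that("column frequencies follow the weighted pseudocount formula", {
  # two sequences over 4 columns, disagreeing at column 2; expected scores
  # recomputed here from first principles
  align <- rbind(encode("ARND"), encode("AKND"))
  bg <- pssmphylo:::BLOSUM62_BACKGROUND
  cond <- pssmphylo:::blosum62_conditional()
  beta <- 10
  got <- pssmphylo:::profile_from_alignment(align, unname(bg), beta)

  # Henikoff: both sequences weight 1 (symmetric); alpha = mean distinct - 1
  alpha <- mean(c(1, 2, 1, 1)) - 1
  expected_col <- function(codes) {
    f <- numeric(20); for (cd in codes) f[cd + 1] <- f[cd + 1] + 0.5
    g <- as.numeric(cond %*% f)
    fp <- (alpha * f + beta * g) / (alpha + beta)
    2 * log2(fp / unname(bg))
  }
  for (j in 1:4) {
    expect_equal(got[j, ], expected_col(align[, j]), tolerance = 1e-10)
  }
})

test_that("background-frequency columns score near zero", {
  # the substitution-matrix prior maps the background onto itself (within
  # the rounding of the published matrix), so an observed distribution at
  # background yields log-odds ~ 0
  bg <- unname(pssmphylo:::BLOSUM62_BACKGROUND)
  cond <- pssmphylo:::blosum62_conditional()
  expect_lt(max(abs(as.numeric(cond %*% bg) - bg)), 0.01)
})

test_that("pseudocount weight shrinks scores toward the prior", {
  align <- rbind(encode("ARNDCQ"), encode("ARNDCQ"), encode("AKNECQ"))
  bg <- unname(pssmphylo:::BLOSUM62_BACKGROUND)
  prior <- pssmphylo:::profile_from_alignment(align, bg, 1e9)
  dev <- vapply(c(1, 5, 20, 100), function(beta) {
    max(abs(pssmphylo:::profile_from_alignment(align, bg, beta) - prior))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("E-value calibration has Gumbel tail properties", {
  set.seed(42)
  db <- lapply(1:20, function(i) seq_record(paste0("d", i),
                                            random_residues(80)))
  prof <- single_seq_pssm(random_residues(50), seed = 9)
  cal <- calibrate_scores(prof, db, n_decoys = 100, rng_seed = 7)
  s <- seq(10, 200, by = 5)
  ev <- evalue(cal, s, n_db = 20)
  # monotone decreasing (strictly, until the tail underflows to zero)
  expect_true(all(diff(ev) <= 0))
  expect_true(all(diff(ev[ev > 1e-300]) < 0))
  expect_equal(evalue(cal, 50, n_db = 40),
               2 * evalue(cal, 50, n_db = 20))      # linear in database size
})

test_that("calibrated E-values are honest on fresh decoys", {
  set.seed(11)
  db <- lapply(1:30, function(i) seq_record(paste0("d", i),
                                            random_residues(100)))
  prof <- single_seq_pssm(random_residues(60), seed = 2)
  cal <- calibrate_scores(prof, db, n_decoys = 1000, rng_seed = 5)
  # fresh decoys, scored per sequence: P(per-sequence E-value <= 0.01)
  # should be about 0.01 under the fitted null
  fresh <- lapply(1:1000, function(i) {
    sample(encode(db[[(i %% 30) + 1]]$residues))
  })
  s <- pssmphylo:::.sw_pssm_scores(fresh, prof$scores, 11, 1)
  p_hat <- mean(evalue(cal, s, n_db = 1) <= 0.01)
  expect_lt(abs(p_hat - 0.01), 0.01)
})

test_that("degenerate calibration and empty databases error", {
  seedrec <- seq_record("s", "AAAAAAAAAAAAAAAAAAAA")
  expect_error(build_pssm(seedrec, list()), "empty")
  # all-identical homopolymer decoys: shuffling changes nothing, zero score
  # variance
  db <- lapply(1:3, function(i) seq_record(paste0("h", i),
                                           strrep("A", 40)))
  prof <- seq_record("s2", strrep("A", 20))
  expect_error(
    build_pssm(prof, db, iterations = 1, n_decoys = 30, rng_seed = 1),
    "zero variance")
})

test_that("build_pssm is deterministic given a seed and enriches homologs", {
  fam <- simulate_family(sim_config(n_leaves = 8, root_length = 60,
                                    expected_identity = 0.6, rng_seed = 21))
  doms <- extract_domains(fam$records, fam$boundaries)
  p1 <- build_pssm(doms[[1]], fam$records, iterations = 2, n_decoys = 40,
                   rng_seed = 77)
  p2 <- build_pssm(doms[[1]], fam$records, iterations = 2, n_decoys = 40,
                   rng_seed = 77)
  expect_identical(p1, p2)
  expect_gt(p1$n_contributing, 0)
})

test_that("a conserved family's profile recovers ancestral residues", {
  fam <- simulate_family(sim_config(n_leaves = 20, root_length = 80,
                                    indel_rate = 0, flank_length = 0,
                                    expected_identity = 0.8, rng_seed = 31))
  doms <- extract_domains(fam$records, fam$boundaries)
  p <- build_pssm(doms[[1]], fam$records, iterations = 2, n_decoys = 40,
                  rng_seed = 5)
  # consensus of the family (the profile argmax) should match the seed at
  # >= 90% of columns under high conservation
  argmax <- AA20[apply(p$scores, 1, which.max)]
  seed_chars <- strsplit(p$seed_residues, "")[[1]]
  expect_gte(mean(argmax == seed_chars), 0.9)
})

test_that("PSSM libraries round-trip through the TSV/JSON format", {
  lib <- random_library(3, len = 25, seed = 8)
  d <- withr::local_tempdir()
  save_pssm_library(lib, d)
  back <- load_pssm_library(d)
  expect_equal(length(back), 3L)
  for (k in 1:3) {
    expect_equal(back$pssms[[k]]$id, lib$pssms[[k]]$id)
    expect_equal(back$pssms[[k]]$seed_residues, lib$pssms[[k]]$seed_residues)
    expect_equal(unname(back$pssms[[k]]$scores),
                 unname(lib$pssms[[k]]$scores), tolerance = 1e-5)
  }
  expect_equal(back$background, lib$background, tolerance = 1e-12)
})
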