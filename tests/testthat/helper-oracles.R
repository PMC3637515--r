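# Shared fixtures and independent oracles for the test suite.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_residues <- function(n) paste(sample(AA20, n, replace = TRUE),
                                     collapse = "")

# A PSSM built from the seed alone (no enrichment beyond itself).
single_seq_pssm <- function(residues, id = "p1", seed = 1) {
  rec <- seq_record(id, residues)
  build_pssm(rec, list(rec), iterations = 1, n_decoys = 30, rng_seed = seed)
}

# Library of M single-sequence profiles from random seeds.
random_library <- function(m, len = 40, seed = 1) {
  set.seed(seed)
  pssms <- lapply(seq_len(m), function(i) {
    pssm(sprintf("p%03d", i),
         matrix(stats::rnorm(len * 20), len, 20),
         random_residues(len))
  })
  pssm_library(pssms)
}

# Independent alignment oracle: plain three-matrix local DP written directly
# from the textbook recurrence, scalar loops, no shared code with the
# package's C++ implementation. Returns the optimal score only.
oracle_local_align <- function(q_codes, pssm_mat, open, extend) {
  n <- length(q_codes)
  L <- nrow(pssm_mat)
  NEG <- -1e30
  M <- matrix(0, n + 1, L + 1)
  X <- matrix(NEG, n + 1, L + 1)
  Y <- matrix(NEG, n + 1, L + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      s <- if (q_codes[i] >= 20) -1 else pssm_mat[j, q_codes[i] + 1]
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - extend)
      M[i + 1, j + 1] <- max(0, s + max(0, M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

encode <- function(residues) {
  match(strsplit(residues, "")[[1]], c(AA20, "X")) - 1L
}

# All 15 unrooted 5-taxon topologies as Newick strings over given labels:
# each topology is an unordered pair of disjoint cherries plus the leftover
# taxon on the internal edge.
five_taxon_topologies <- function(labs) {
  out <- character(0)
  cmb <- utils::combn(5, 2)
  for (a in seq_len(ncol(cmb) - 1)) {
    for (b in (a + 1):ncol(cmb)) {
      p1 <- cmb[, a]; p2 <- cmb[, b]
      if (length(intersect(p1, p2))) next
      single <- setdiff(1:5, c(p1, p2))
      out <- c(out, sprintf("((%s,%s),(%s,%s),%s);",
                            labs[p1[1]], labs[p1[2]],
                            labs[p2[1]], labs[p2[2]], labs[single]))
    }
  }
  out
}

# Ordinary-least-squares branch lengths for a topology given a distance
# matrix; returns list(fit_error, total_length). Independent oracle for
# minimum-evolution comparison.
ols_tree_fit <- function(nwk, dm) {
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  labs <- rownames(dm)
  n <- length(labs)
  pairs <- t(combn(n, 2))
  # design matrix: rows = taxon pairs, cols = edges on the path
  A <- matrix(0, nrow(pairs), nrow(tr$edge))
  for (k in seq_len(nrow(pairs))) {
    i <- match(labs[pairs[k, 1]], tr$tip.label)
    j <- match(labs[pairs[k, 2]], tr$tip.label)
    np <- ape::nodepath(tr, i, j)
    for (e in seq_len(nrow(tr$edge))) {
      a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
      ia <- match(a, np); ib <- match(b, np)
      if (!is.na(ia) && !is.na(ib) && abs(ia - ib) == 1) A[k, e] <- 1
    }
  }
  d <- dm[pairs]
  fit <- stats::lm.fit(A, d)
  resid <- d - A %*% fit$coefficients
  list(sse = sum(resid^2), total = sum(pmax(fit$coefficients, 0)),
       lengths = fit$coefficients)
}

# Direct bipartition tally over trees: named vector split-key -> count,
# computed with ape::prop.part (independent of the package's traversal).
oracle_split_counts <- function(trees) {
  all_keys <- unlist(lapply(trees, function(tr) {
    labs <- sort(tr$tip.label)
    ref <- labs[1]
    pp <- ape::prop.part(tr)
    tipl <- attr(pp, "labels")
    keys <- vapply(pp, function(part) {
      side <- tipl[part]
      if (length(side) < 2 || length(side) > length(labs) - 2) return(NA_character_)
      if (ref %in% side) side <- setdiff(labs, side)
      if (length(side) < 2 || length(side) > length(labs) - 2) return(NA_character_)
      paste(sort(side), collapse = "\r")
    }, character(1))
    unique(keys[!is.na(keys)])
  }))
  table(all_keys)
}

# Composite matrix over random queries/profiles (no retention), for the
# resampling tests.
fixture_matrix <- function(seed = 1, n = 6, m = 8) {
  lib <- random_library(m, len = 20, seed = seed)
  set.seed(seed + 500)
  qs <- lapply(seq_len(n), function(i) seq_record(sprintf("q%02d", i),
                                                  random_residues(30)))
  build_composite_matrix(qs, lib, b_fraction = 1.0)
}

# Random additive distance matrix from a random tree with strictly positive
# branch lengths; returns list(tree, dm).
random_additive_case <- function(n_leaves, seed) {
  tr <- sample_tree(n_leaves, branch_mean = 0.5, rng_seed = seed)
  tr$edge.length <- tr$edge.length + 0.05   # strictly positive
  dm <- stats::cophenetic(tr)
  list(tree = tr, dm = dm)
}
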