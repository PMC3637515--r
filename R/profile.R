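#' Position-specific scoring matrices
#'
#' A `pssm` holds one position-specific score model built from a seed domain
#' region: an `L x 20` matrix of real-valued log-odds scores in half-bit
#' units (columns in the fixed residue order `A R N D C Q E G H I L K M F P
#' S T W Y V`), the seed residues the profile's columns correspond to, and
#' the number of database sequences that contributed to it.
#'
#' @param id Profile id (usually the seed domain's parent id).
#' @param scores `L x 20` numeric matrix of half-bit log-odds scores.
#' @param seed_residues Length-`L` residue string of the seed.
#' @param n_contributing Count of database sequences included in the build.
#' @return A `pssm` object.
#' @export
pssm <- function(id, scores, seed_residues, n_contributing = 0L) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) stop_("pssm scores must have 20 columns")
  if (nrow(scores) < 1L) stop_("pssm must have at least one column (L >= 1)")
  if (!all(is.finite(scores))) stop_("pssm scores must be finite")
  seed_residues <- toupper(seed_residues)
  if (nchar(seed_residues) != nrow(scores)) {
    stop_("seed_residues length must equal the number of profile positions")
  }
  dimnames(scores) <- list(NULL, AA_ORDER)
  structure(list(id = id, length = nrow(scores), scores = scores,
                 seed_residues = seed_residues,
                 n_contributing = as.integer(n_contributing)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm>", x$id, "-", x$length, "columns,",
      x$n_contributing, "contributing sequences\n")
  invisible(x)
}

#' @param pssms List of [pssm()] objects with unique ids.
#' @param background Length-20 positive frequency vector summing to 1.
#' @param build_params List of build settings (recorded verbatim).
#' @rdname pssm
#' @export
pssm_library <- function(pssms, background = BLOSUM62_BACKGROUND,
                         build_params = list()) {
  ids <- vapply(pssms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_("duplicate pssm id: '", ids[duplicated(ids)][1], "'")
  }
  background <- as.numeric(background)
  if (length(background) != 20L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-12) {
    stop_("background must be 20 positive frequencies summing to 1")
  }
  names(background) <- AA_ORDER
  structure(list(pssms = pssms, background = background,
                 build_params = build_params),
            class = "pssm_library")
}

#' @export
print.pssm_library <- function(x, ...) {
  cat("<pssm_library>", length(x$pssms), "profiles\n")
  invisible(x)
}

#' @export
length.pssm_library <- function(x) length(x$pssms)

library_ids <- function(library) {
  vapply(library$pssms, `[[`, character(1), "id")
}

# BLOSUM62 row profile of a seed: the iteration-1 "profile" is just the
# substitution-matrix scores of each seed residue. X rows score 0.
seed_score_profile <- function(residues) {
  codes <- encode_residues(residues)
  B <- blosum62_matrix()
  t(vapply(codes, function(code) {
    if (code >= 20L) rep(0, 20L) else B[code + 1L, ]
  }, numeric(20L)))
}

#' Empirical E-value calibration from shuffled decoys
#'
#' Fits a Gumbel (type-I extreme value) distribution, by the method of
#' moments, to the maximal local-alignment scores of residue-shuffled
#' database sequences against a score profile. The fitted location \eqn{\mu}
#' and scale \eqn{\lambda} convert a raw score into an E-value over a
#' database of `n_db` sequences:
#' \deqn{E(s) = n_{db} (1 - \exp(-\exp(-\lambda (s - \mu))))}
#'
#' @param scores An `L x 20` score matrix or a [pssm()].
#' @param target_db List of [seq_record()]s whose shuffles serve as decoys.
#' @param n_decoys Number of decoys (at least 30).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param rng_seed Optional integer seed for the decoy shuffles.
#' @return A `score_calibration` with fields `mu`, `lambda`, `n_decoys`.
#' @export
calibrate_scores <- function(scores, target_db, n_decoys = 200L,
                             gap_open = 11, gap_extend = 1, rng_seed = NULL) {
  if (inherits(scores, "pssm")) scores <- scores$scores
  if (length(target_db) == 0L) stop_("target_db is empty")
  if (n_decoys < 30L) stop_("n_decoys must be at least 30")
  db_codes <- lapply(target_db, function(r) encode_residues(r$residues))
  decoys <- with_rng_seed(rng_seed, {
    idx <- rep_len(seq_along(db_codes), n_decoys)
    lapply(idx, function(i) sample(db_codes[[i]]))
  })
  s <- .sw_pssm_scores(decoys, scores, gap_open, gap_extend)
  if (stats::sd(s) < 1e-9) {
    stop_("degenerate calibration: decoy scores have zero variance; ",
          "increase n_decoys or check the profile")
  }
  lambda <- pi / (stats::sd(s) * sqrt(6))
  mu <- mean(s) - 0.5772156649015329 / lambda
  structure(list(mu = mu, lambda = lambda, n_decoys = as.integer(n_decoys)),
            class = "score_calibration")
}

#' @param calibration A `score_calibration` from [calibrate_scores()].
#' @param score Raw alignment score(s).
#' @param n_db Database size the E-value is scaled to.
#' @rdname calibrate_scores
#' @export
evalue <- function(calibration, score, n_db) {
  stopifnot(inherits(calibration, "score_calibration"))
  n_db * (1 - exp(-exp(-calibration$lambda * (score - calibration$mu))))
}

# Henikoff position-based sequence weights for an alignment given as a
# matrix of residue codes (rows = sequences, cols = profile positions,
# NA = gap/uncovered). Per column each of the r distinct residues shares
# weight 1/r among the sequences carrying it; sequence weights are summed
# over covered columns and normalized to mean 1.
henikoff_weights <- function(align) {
  ns <- nrow(align)
  if (ns == 1L) return(1)
  w <- numeric(ns)
  for (j in seq_len(ncol(align))) {
    col <- align[, j]
    obs <- which(!is.na(col))
    if (!length(obs)) next
    counts <- table(col[obs])
    r <- length(counts)
    w[obs] <- w[obs] + 1 / (r * as.numeric(counts[as.character(col[obs])]))
  }
  if (all(w == 0)) w[] <- 1
  w / mean(w[w > 0])
}

# Column frequencies + PSI-BLAST-style pseudocounts -> half-bit log-odds.
# alpha = mean distinct residues per column - 1; beta = pseudocount_weight.
profile_from_alignment <- function(align, background, pseudocount_weight) {
  L <- ncol(align)
  w <- henikoff_weights(align)
  cond <- blosum62_conditional()
  distinct <- vapply(seq_len(L), function(j) {
    length(unique(align[!is.na(align[, j]), j]))
  }, numeric(1))
  alpha <- max(mean(distinct) - 1, 0)
  beta <- pseudocount_weight
  scores <- matrix(0, L, 20L)
  for (j in seq_len(L)) {
    col <- align[, j]
    obs <- which(!is.na(col) & col < 20L)   # X carries no count
    f <- numeric(20L)
    if (length(obs)) {
      wt <- w[obs]
      for (k in seq_along(obs)) {
        a <- col[obs[k]] + 1L
        f[a] <- f[a] + wt[k]
      }
      f <- f / sum(f)
      g <- as.numeric(cond %*% f)           # substitution-matrix prior
    } else {
      f <- background
      g <- background
    }
    fp <- (alpha * f + beta * g) / (alpha + beta)
    scores[j, ] <- 2 * log2(fp / background)
  }
  scores
}

#' Build a PSSM from a seed domain against a target database
#'
#' Iterative profile construction in the PSI-BLAST mould. Iteration 1 aligns
#' the seed region against every database sequence under BLOSUM62 with
#' affine gaps; sequences whose empirical E-value (Gumbel calibration on
#' residue-shuffled decoys, see [calibrate_scores()]) is at or below
#' `evalue_threshold` are included. Included alignments are stacked on the
#' seed's columns, residue frequencies are computed with Henikoff
#' position-based sequence weighting, mixed with substitution-matrix
#' pseudocounts (prior weight `pseudocount_weight` against the effective
#' observation count, the mean number of distinct residues per column minus
#' one), and converted to half-bit log-odds against the background. Later
#' iterations repeat the search with the current profile. The seed itself is
#' always included, so every column is defined.
#'
#' @param seed A `domain_region` (from [extract_domains()]) or
#'   [seq_record()] supplying the profile columns.
#' @param target_db Non-empty list of [seq_record()]s to enrich against.
#' @param evalue_threshold Inclusion threshold (default `7e-13`, suited to a
#'   small dedicated target database; thresholds scale with database size).
#' @param iterations Number of search-and-rebuild rounds (default 3).
#' @param pseudocount_weight Prior weight \eqn{\beta} (default 10).
#' @param gap_open,gap_extend Affine gap penalties (default 11 / 1).
#' @param n_decoys Decoys per calibration round.
#' @param rng_seed Optional integer seed (decoy shuffles); the build is
#'   deterministic given the seed.
#' @return A [pssm()].
#' @export
build_pssm <- function(seed, target_db, evalue_threshold = 7e-13,
                       iterations = 3L, pseudocount_weight = 10,
                       gap_open = 11, gap_extend = 1, n_decoys = 200L,
                       rng_seed = NULL) {
  seed <- as_seq_record(seed)
  if (length(target_db) == 0L) stop_("target_db is empty")
  if (evalue_threshold <= 0) stop_("evalue_threshold must be positive")
  if (iterations < 1L) stop_("iterations must be >= 1")
  L <- nchar(seed$residues)
  seed_codes <- encode_residues(seed$residues)
  db_codes <- lapply(target_db, function(r) encode_residues(r$residues))
  n_db <- length(target_db)
  seeds <- derive_seeds(rng_seed, iterations)

  profile <- seed_score_profile(seed$residues)
  n_contributing <- 0L
  for (iter in seq_len(iterations)) {
    calib <- calibrate_scores(profile, target_db, n_decoys,
                              gap_open, gap_extend, rng_seed = seeds[[iter]])
    raw <- .sw_pssm_scores(db_codes, profile, gap_open, gap_extend)
    included <- which(evalue(calib, raw, n_db) <= evalue_threshold)
    n_contributing <- length(included)
    # stack included alignments on the seed's columns
    align <- matrix(NA_integer_, nrow = 1L + length(included), ncol = L)
    align[1L, ] <- seed_codes
    for (k in seq_along(included)) {
      hit <- .sw_pssm_align(db_codes[[included[k]]], profile,
                            gap_open, gap_extend, TRUE)
      m <- hit$ppos > 0L & hit$qpos > 0L
      align[k + 1L, hit$ppos[m]] <- db_codes[[included[k]]][hit$qpos[m]]
    }
    profile <- profile_from_alignment(align, unname(BLOSUM62_BACKGROUND),
                                      pseudocount_weight)
  }
  pssm(seed$id, profile, seed$residues, n_contributing)
}

#' Build the full PSSM library for a set of seed domains
#'
#' Applies [build_pssm()] to each seed region, preserving order, and wraps
#' the result in a [pssm_library()] that records the build parameters.
#'
#' @param seeds List of `domain_region`s or [seq_record()]s.
#' @param target_db List of [seq_record()]s.
#' @inheritParams build_pssm
#' @return A [pssm_library()].
#' @export
build_pssm_library <- function(seeds, target_db, evalue_threshold = 7e-13,
                               iterations = 3L, pseudocount_weight = 10,
                               gap_open = 11, gap_extend = 1,
                               n_decoys = 200L, rng_seed = NULL) {
  seeds_rng <- derive_seeds(rng_seed, length(seeds))
  pssms <- lapply(seq_along(seeds), function(i) {
    build_pssm(seeds[[i]], target_db, evalue_threshold, iterations,
               pseudocount_weight, gap_open, gap_extend, n_decoys,
               rng_seed = seeds_rng[[i]])
  })
  pssm_library(pssms, build_params = list(
    evalue_threshold = evalue_threshold, iterations = iterations,
    pseudocount_weight = pseudocount_weight, gap_open = gap_open,
    gap_extend = gap_extend, n_decoys = n_decoys, rng_seed = rng_seed))
}

#' Save or load a PSSM library as TSV matrices plus a JSON manifest
#'
#' The on-disk format is a directory holding one `<id>.tsv` per profile
#' (L rows by 20 columns, header = amino-acid order, preceded by `#`
#' comment lines with the seed residues and contribution count) and a
#' `manifest.json` with ids, lengths, background and build parameters.
#' Externally built profiles in the same layout load identically.
#'
#' @param library A [pssm_library()].
#' @param dir Directory path.
#' @return `save_pssm_library()` returns `dir` invisibly;
#'   `load_pssm_library()` returns a [pssm_library()].
#' @export
save_pssm_library <- function(library, dir) {
  stopifnot(inherits(library, "pssm_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- library_ids(library)
  for (p in library$pssms) {
    f <- file.path(dir, paste0(p$id, ".tsv"))
    con <- file(f, "w")
    writeLines(c(paste0("# seed_residues: ", p$seed_residues),
                 paste0("# n_contributing: ", p$n_contributing)), con)
    utils::write.table(round(p$scores, 6), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    close(con)
  }
  manifest <- list(ids = ids,
                   lengths = vapply(library$pssms, `[[`, integer(1), "length"),
                   background = as.list(library$background),
                   build_params = library$build_params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_pssm_library
#' @export
load_pssm_library <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pssms <- lapply(manifest$ids, function(id) {
    f <- file.path(dir, paste0(id, ".tsv"))
    hdr <- readLines(f, n = 2L)
    seed_res <- sub("^# seed_residues: ", "", hdr[1])
    n_contr <- as.integer(sub("^# n_contributing: ", "", hdr[2]))
    scores <- as.matrix(utils::read.delim(f, comment.char = "#"))
    pssm(id, scores, seed_res, n_contr)
  })
  bg <- unlist(manifest$background)[AA_ORDER]
  pssm_library(pssms, background = bg / sum(bg),
               build_params = as.list(manifest$build_params))
}
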