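#' Shuffle a sequence's residue order
#'
#' Uniformly permutes the linear order of a sequence's residues (sampling
#' without replacement), preserving its length and amino-acid composition —
#' the null model for the randomization test.
#'
#' @param record A [seq_record()].
#' @param rng_seed Optional integer seed.
#' @return A `seq_record` with the same id and permuted residues.
#' @export
shuffle_sequence <- function(record, rng_seed = NULL) {
  record <- as_seq_record(record)
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  shuffled <- with_rng_seed(rng_seed, sample(chars))
  seq_record(record$id, paste(shuffled, collapse = ""), record$description)
}

#' Difference Ratio randomization statistic
#'
#' Quantifies per-coordinate signal-to-noise in the composite score matrix.
#' Each replicate shuffles every query's residue order (one shuffle per
#' query per replicate) and aligns the shuffles against all M profiles,
#' giving a null composite score per coordinate. Over `n_replicates`
#' replicates the per-coordinate mean and standard deviation of the null
#' scores are recorded, and the Difference Ratio is
#' \deqn{DR = (composite_{wt} - \overline{composite}_{random}) / SD_{random}}
#' a z-score of the wild-type score against its randomization null. No
#' retention rule is applied anywhere in this computation: both wild-type
#' and null scores are raw composites. The SD uses the population (n)
#' divisor by default. Coordinates with zero null SD get DR 0 when the
#' wild-type score equals the null mean, otherwise the sentinel `sd_zero_cap`.
#'
#' @param queries List of [seq_record()]s.
#' @param library A [pssm_library()].
#' @param gap_open,gap_extend Affine gap penalties.
#' @param n_replicates Number of shuffle replicates (>= 2; default 100).
#' @param rng_seed Optional integer seed; the whole computation is
#'   deterministic given the seed.
#' @param sd_divisor `"population"` (n, default) or `"sample"` (n - 1).
#' @param sd_zero_cap Sentinel DR for zero-SD, nonzero-signal coordinates.
#' @return A `difference_ratio_matrix`: `wt`, `rand_mean`, `rand_sd`, `dr`
#'   (all N x M with query/profile dimnames) and `n_replicates`.
#' @export
#' @examples
#' # DR = (5000 - 1000) / 500 = 8 for a single hand-set coordinate
#' (5000 - 1000) / 500
difference_ratio <- function(queries, library, gap_open = 11, gap_extend = 1,
                             n_replicates = 100L, rng_seed = NULL,
                             sd_divisor = c("population", "sample"),
                             sd_zero_cap = 1e4) {
  stopifnot(inherits(library, "pssm_library"))
  sd_divisor <- match.arg(sd_divisor)
  if (n_replicates < 2L) stop_("n_replicates must be >= 2")
  qids <- check_unique_ids(queries)
  mids <- library_ids(library)
  n <- length(queries)
  m <- length(library)

  wt <- composite_values(queries, library, gap_open, gap_extend)
  # Welford streaming moments: numerically stable, and constant replicate
  # scores (shuffle fixed points) give an exact zero SD
  run_mean <- matrix(0, n, m)
  run_ss <- matrix(0, n, m)
  rep_seeds <- derive_seeds(rng_seed, n_replicates)
  for (r in seq_len(n_replicates)) {
    shuffled <- with_rng_seed(rep_seeds[[r]],
                              lapply(queries, shuffle_sequence))
    v <- composite_values(shuffled, library, gap_open, gap_extend)
    delta <- v - run_mean
    run_mean <- run_mean + delta / r
    run_ss <- run_ss + delta * (v - run_mean)
  }
  rand_mean <- run_mean
  denom <- if (sd_divisor == "population") n_replicates else n_replicates - 1
  rand_sd <- sqrt(pmax(run_ss, 0) / denom)

  dr <- matrix(0, n, m)
  pos <- rand_sd > 0
  dr[pos] <- (wt[pos] - rand_mean[pos]) / rand_sd[pos]
  degen <- !pos & abs(wt - rand_mean) > 1e-9
  dr[degen] <- sd_zero_cap
  dn <- list(qids, mids)
  dimnames(wt) <- dimnames(rand_mean) <- dimnames(rand_sd) <-
    dimnames(dr) <- dn
  structure(list(wt = wt, rand_mean = rand_mean, rand_sd = rand_sd,
                 dr = dr, n_replicates = as.integer(n_replicates)),
            class = "difference_ratio_matrix")
}

#' @export
print.difference_ratio_matrix <- function(x, ...) {
  cat("<difference_ratio_matrix>", nrow(x$dr), "queries x", ncol(x$dr),
      "profiles,", x$n_replicates, "replicates\n")
  invisible(x)
}

#' Log display scale for Difference Ratios
#'
#' `log10(max(dr, 1))` for rendering and export; DR 0 (or any value below
#' 1) displays as 0, DR 1000 as 3. The raw DR values stay untouched in the
#' matrix.
#'
#' @param dr Difference Ratio value(s).
#' @return Log-scaled value(s).
#' @export
dr_log_display <- function(dr) {
  log10(pmax(dr, 1))
}

#' Export a Difference Ratio matrix as TSV
#'
#' One row per coordinate: query id, profile id, wild-type composite, null
#' mean and SD, DR and its log display value.
#'
#' @param x A `difference_ratio_matrix`.
#' @param path Output path.
#' @return The data frame written, invisibly.
#' @export
write_dr_tsv <- function(x, path) {
  stopifnot(inherits(x, "difference_ratio_matrix"))
  idx <- expand.grid(i = seq_len(nrow(x$dr)), j = seq_len(ncol(x$dr)))
  df <- data.frame(query_id = rownames(x$dr)[idx$i],
                   pssm_id = colnames(x$dr)[idx$j],
                   composite_wt = x$wt[cbind(idx$i, idx$j)],
                   rand_mean = x$rand_mean[cbind(idx$i, idx$j)],
                   rand_sd = x$rand_sd[cbind(idx$i, idx$j)],
                   dr = x$dr[cbind(idx$i, idx$j)],
                   dr_log = dr_log_display(x$dr[cbind(idx$i, idx$j)]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
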