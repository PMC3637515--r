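#' Align a full-length query against a PSSM
#'
#' Optimal local alignment of a query sequence against a position-specific
#' score matrix by three-state affine-gap dynamic programming, with the
#' composite alignment statistics used downstream: percent identity (matches
#' to the profile's seed residues over all alignment columns, gap columns
#' included), percent coverage (distinct profile positions in the alignment
#' over the profile length `L`), and their product, the composite score in
#' `[0, 10000]`. A query with no positive-scoring alignment returns the
#' empty alignment with composite 0.
#'
#' @param query A [seq_record()].
#' @param pssm A [pssm()].
#' @param gap_open,gap_extend Affine gap penalties; the first gap column
#'   costs `gap_open`, each further column `gap_extend`. Requires
#'   `gap_open >= gap_extend > 0`.
#' @return An `alignment_result`: `query_id`, `pssm_id`, `raw_score`,
#'   half-open `query_span`/`pssm_span`, an `aligned_pairs` matrix (columns
#'   `query`, `pssm`; 1-based positions, `NA` = gap), `percent_identity`,
#'   `percent_coverage` and `composite`.
#' @export
#' @examples
#' seed <- seq_record("d1", "MKVLWAALLV")
#' p <- build_pssm(seed, list(seed), iterations = 1, n_decoys = 30,
#'                 rng_seed = 1)
#' align_query_to_pssm(seed, p)$composite
align_query_to_pssm <- function(query, pssm, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(pssm, "pssm"))
  query <- as_seq_record(query)
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    stop_("need gap_open >= gap_extend > 0")
  }
  codes <- encode_residues(query$residues)
  hit <- .sw_pssm_align(codes, pssm$scores, gap_open, gap_extend, TRUE)
  qpos <- hit$qpos
  ppos <- hit$ppos
  pairs <- cbind(query = ifelse(qpos > 0L, qpos, NA_integer_),
                 pssm = ifelse(ppos > 0L, ppos, NA_integer_))
  res <- structure(list(
    query_id = query$id, pssm_id = pssm$id, raw_score = hit$score,
    query_span = if (length(qpos)) c(min(qpos[qpos > 0L]) - 1L,
                                     max(qpos[qpos > 0L])) else c(0L, 0L),
    pssm_span = if (length(ppos)) c(min(ppos[ppos > 0L]) - 1L,
                                    max(ppos[ppos > 0L])) else c(0L, 0L),
    aligned_pairs = pairs,
    query_residues = query$residues),
    class = "alignment_result")
  stats <- alignment_stats(res, pssm)
  res$percent_identity <- stats[["percent_identity"]]
  res$percent_coverage <- stats[["percent_coverage"]]
  res$composite <- stats[["composite"]]
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> %s vs %s: score %.1f, id %.1f%%, cov %.1f%%, composite %.1f\n",
              x$query_id, x$pssm_id, x$raw_score, x$percent_identity,
              x$percent_coverage, x$composite))
  invisible(x)
}

#' Composite alignment statistics
#'
#' Percent identity is `100 *` (aligned columns where the query residue
#' equals the profile's seed residue) `/` (total alignment columns, gaps
#' included); percent coverage is `100 *` (distinct profile positions
#' aligned) `/ L`. The composite score is the plain product of the two
#' percentages, so a perfect full-length self-alignment scores
#' `100 * 100 = 10000`.
#'
#' @param alignment An `alignment_result` from [align_query_to_pssm()].
#' @param pssm The [pssm()] it was aligned against.
#' @return Named numeric vector `percent_identity`, `percent_coverage`,
#'   `composite`.
#' @export
alignment_stats <- function(alignment, pssm) {
  pairs <- alignment$aligned_pairs
  ncols <- nrow(pairs)
  if (ncols == 0L) {
    return(c(percent_identity = 0, percent_coverage = 0, composite = 0))
  }
  seed_chars <- strsplit(pssm$seed_residues, "", fixed = TRUE)[[1]]
  q_chars <- strsplit(alignment$query_residues, "", fixed = TRUE)[[1]]
  both <- !is.na(pairs[, "query"]) & !is.na(pairs[, "pssm"])
  n_ident <- sum(q_chars[pairs[both, "query"]] ==
                 seed_chars[pairs[both, "pssm"]])
  pid <- 100 * n_ident / ncols
  # profile positions opposite a query gap still count as covered
  covered <- pairs[!is.na(pairs[, "pssm"]), "pssm"]
  pcov <- 100 * length(unique(covered)) / pssm$length
  c(percent_identity = pid, percent_coverage = pcov,
    composite = pid * pcov)
}

#' Log scale for composite scores
#'
#' Maps a composite score in `[0, 10000]` to the `[0, 4]` display scale as
#' `log10(max(composite, 1))`: 0 maps to 0, the maximal score 10000 maps to
#' exactly 4.
#'
#' @param composite Composite score(s) in `[0, 10000]`.
#' @return Log-scaled value(s) in `[0, 4]`.
#' @export
#' @examples
#' log_scale(c(0, 100, 10000))
log_scale <- function(composite) {
  if (any(composite < 0)) stop_("composite scores cannot be negative")
  log10(pmax(composite, 1))
}

#' Export alignment results as TSV
#'
#' @param alignments List of `alignment_result`s.
#' @param path Output TSV path (or connection).
#' @return The data frame written, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  df <- do.call(rbind, lapply(alignments, function(a) {
    data.frame(query_id = a$query_id, pssm_id = a$pssm_id,
               raw_score = a$raw_score, percent_identity = a$percent_identity,
               percent_coverage = a$percent_coverage, composite = a$composite)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
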