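#' Build the N x M composite score matrix
#'
#' Aligns every query against every profile in the library and records the
#' composite score (percent identity times percent coverage) per cell. Per
#' query (row-wise), only the top-scoring `ceil(b_fraction * M)` profiles
#' are retained — the report-limit rule; the default keeps the top 75% of
#' profiles. Cells outside the retained set are stored as 0 and flagged in
#' the `retained` mask. Ties at the retention boundary are broken toward
#' the smaller profile index.
#'
#' @param queries List of [seq_record()]s (N >= 4).
#' @param library A [pssm_library()] (M >= 2).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param b_fraction Fraction of profiles retained per query, in `(0, 1]`.
#' @return A `composite_matrix`: `values` (N x M, dimnames = query/profile
#'   ids), `retained` (logical N x M), `b_fraction`.
#' @export
build_composite_matrix <- function(queries, library, gap_open = 11,
                                   gap_extend = 1, b_fraction = 0.75) {
  stopifnot(inherits(library, "pssm_library"))
  if (length(queries) < 4L) stop_("need at least 4 queries")
  if (length(library) < 2L) stop_("need at least 2 profiles")
  if (!(b_fraction > 0 && b_fraction <= 1)) {
    stop_("b_fraction must be in (0, 1]")
  }
  qids <- check_unique_ids(queries)
  raw <- composite_values(queries, library, gap_open, gap_extend)
  dimnames(raw) <- list(qids, library_ids(library))
  apply_retention(raw, b_fraction)
}

# Raw N x M composite values, no retention (also used by the randomization
# test, which scores raw composites).
composite_values <- function(queries, library, gap_open, gap_extend) {
  n <- length(queries)
  m <- length(library)
  vals <- matrix(0, n, m)
  for (j in seq_len(m)) {
    p <- library$pssms[[j]]
    for (i in seq_len(n)) {
      vals[i, j] <- align_query_to_pssm(queries[[i]], p, gap_open,
                                        gap_extend)$composite
    }
  }
  vals
}

apply_retention <- function(values, b_fraction) {
  m <- ncol(values)
  keep_n <- ceiling(b_fraction * m)
  retained <- matrix(FALSE, nrow(values), m, dimnames = dimnames(values))
  out <- values
  for (i in seq_len(nrow(values))) {
    # order by descending composite, ties toward the smaller profile index
    ord <- order(-values[i, ], seq_len(m))
    keep <- ord[seq_len(keep_n)]
    retained[i, keep] <- TRUE
    out[i, !retained[i, ]] <- 0
  }
  structure(list(values = out, retained = retained,
                 b_fraction = b_fraction),
            class = "composite_matrix")
}

#' @export
print.composite_matrix <- function(x, ...) {
  cat("<composite_matrix>", nrow(x$values), "queries x", ncol(x$values),
      "profiles, b_fraction", x$b_fraction, "\n")
  invisible(x)
}

#' Euclidean distance matrix from a composite matrix
#'
#' The distance between queries i and j is the Euclidean norm of the
#' difference of their post-retention composite rows over all M profile
#' columns (masked-out cells contribute 0).
#'
#' @param matrix A `composite_matrix` from [build_composite_matrix()], or a
#'   plain numeric matrix of row vectors.
#' @return Symmetric N x N numeric matrix with zero diagonal, dimnames =
#'   query ids.
#' @export
euclidean_distances <- function(matrix) {
  vals <- if (inherits(matrix, "composite_matrix")) matrix$values else matrix
  d <- as.matrix(stats::dist(vals, method = "euclidean"))
  dimnames(d) <- list(rownames(vals), rownames(vals))
  d
}

#' Scale a distance matrix to the unit interval
#'
#' Divides every entry by the maximum entry, for display and reporting
#' (drawn trees are annotated with distances scaled between 0 and 1); tree
#' inference always consumes unscaled distances.
#'
#' @param dm Symmetric non-negative distance matrix.
#' @return The matrix divided by its maximum.
#' @export
scale_unit <- function(dm) {
  mx <- max(dm)
  if (mx <= 0) stop_("cannot unit-scale an all-zero distance matrix")
  dm / mx
}

#' Composite and distance matrix file formats
#'
#' The composite matrix is written as TSV (queries as rows, header of
#' profile ids); distance matrices use the square PHYLIP format (taxon
#' count on the first line, then one row per taxon: id followed by N
#' distances) for interoperability with `neighbor`/`consense`-style tools.
#'
#' @param x A `composite_matrix` (TSV) or distance matrix (PHYLIP).
#' @param path File path.
#' @param b_fraction Retention fraction recorded when reading a TSV back.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_composite_tsv <- function(x, path) {
  stopifnot(inherits(x, "composite_matrix"))
  df <- data.frame(query_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_composite_tsv
#' @export
read_composite_tsv <- function(path, b_fraction = 1) {
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  structure(list(values = vals,
                 retained = matrix(TRUE, nrow(vals), ncol(vals),
                                   dimnames = dimnames(vals)),
                 b_fraction = b_fraction),
            class = "composite_matrix")
}

#' @rdname write_composite_tsv
#' @export
write_phylip_dist <- function(x, path) {
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(x)))
  lines <- c(format(nrow(x)),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(sprintf("%-10s", ids[i]),
                       sprintf("%.6f", x[i, ])), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_composite_tsv
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  ids <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    ids[i] <- parts[1]
    m[i, ] <- as.numeric(parts[-1])
  }
  dimnames(m) <- list(ids, ids)
  m
}
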