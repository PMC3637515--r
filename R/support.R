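#' Jackknife replicates of the composite matrix
#'
#' Each replicate subsamples `ceil(fraction * M)` profile columns of the
#' (post-retention) composite matrix without replacement, recomputes the
#' Euclidean distance matrix on the subsampled columns, and infers a
#' Neighbor-Joining tree. The default resamples 80% of the columns; branch
#' support is conventionally summarized over 5000 replicates (scale down
#' for interactive work). Deterministic given `rng_seed`.
#'
#' @param matrix A `composite_matrix` from [build_composite_matrix()].
#' @param fraction Column fraction per replicate, in `(0, 1]`.
#' @param n_replicates Number of replicate trees.
#' @param rng_seed Optional integer seed.
#' @return List of `phylo` replicate trees.
#' @export
jackknife_replicates <- function(matrix, fraction = 0.8,
                                 n_replicates = 5000L, rng_seed = NULL) {
  stopifnot(inherits(matrix, "composite_matrix"))
  if (!(fraction > 0 && fraction <= 1)) stop_("fraction must be in (0, 1]")
  if (n_replicates < 1L) stop_("n_replicates must be >= 1")
  m <- ncol(matrix$values)
  k <- ceiling(fraction * m)
  if (k < 2L) stop_("fraction ", fraction, " leaves fewer than 2 of ", m,
                    " columns")
  with_rng_seed(rng_seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(m, k)
      nj_tree(euclidean_distances(matrix$values[, cols, drop = FALSE]))
    })
  })
}

# Tally canonical split keys over a list of trees on a common leaf set.
count_splits <- function(trees) {
  ref_tips <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, ref_tips) ||
        length(tr$tip.label) != length(ref_tips)) {
      stop_("replicate trees must share an identical leaf set")
    }
  }
  tab <- table(unlist(lapply(trees, tree_splits)))
  list(counts = tab, n = length(trees), tips = ref_tips)
}

#' Majority-rule consensus of replicate trees
#'
#' The consensus contains exactly the non-trivial bipartitions present in
#' strictly more than half of the input trees (all compatible by
#' construction), plus the trivial ones; it may be multifurcating. Each
#' retained branch carries its support: the percentage of replicates
#' containing the bipartition, rounded to one decimal.
#'
#' @param trees Non-empty list of `phylo` trees on a common leaf set.
#' @return A `supported_tree`: `tree` (`phylo` with support values as
#'   internal node labels), `support` (named vector, split key ->
#'   percentage), `n_replicates`.
#' @export
majority_consensus <- function(trees) {
  if (length(trees) < 1L) stop_("need at least one tree")
  cs <- count_splits(trees)
  maj <- cs$counts[2 * cs$counts > cs$n]
  pct <- round(100 * as.numeric(maj) / cs$n, 1)
  names(pct) <- names(maj)
  tree <- splits_to_tree(names(maj), cs$tips, labels = format_pct(pct))
  supported_tree(tree, pct, cs$n)
}

format_pct <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sprintf("%.1f", x))
}

# Build a (possibly multifurcating) tree from a set of pairwise-compatible
# canonical splits. Each split key is the "\r"-joined sorted tip side not
# containing the reference taxon; these sides form a laminar family, so the
# tree is the nesting forest of the sides with remaining tips attached to
# their smallest enclosing clade.
splits_to_tree <- function(keys, tips, labels = NULL) {
  sides <- lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  sizes <- lengths(sides)
  ord <- order(sizes)               # smallest first
  sides <- sides[ord]
  if (!is.null(labels)) labels <- labels[ord]
  nclade <- length(sides)
  # parent clade: smallest strictly-containing side (0 = root)
  parent <- integer(nclade)
  for (i in seq_len(nclade)) {
    parent[i] <- 0L
    for (j in seq_len(nclade)) {
      if (j == i || length(sides[[j]]) <= length(sides[[i]])) next
      if (all(sides[[i]] %in% sides[[j]])) { parent[i] <- j; break }
    }
  }
  tip_parent <- vapply(tips, function(tp) {
    holders <- which(vapply(sides, function(s) tp %in% s, logical(1)))
    if (length(holders)) holders[1] else 0L
  }, integer(1))
  build <- function(ci) {
    kids <- c(tips[tip_parent == ci],
              vapply(which(parent == ci), build, character(1)))
    if (ci == 0L) return(paste0("(", paste(kids, collapse = ","), ");"))
    lab <- if (!is.null(labels)) labels[ci] else ""
    paste0("(", paste(kids, collapse = ","), ")", lab)
  }
  ape::read.tree(text = build(0L))
}

supported_tree <- function(tree, support, n_replicates) {
  structure(list(tree = tree, support = support,
                 n_replicates = as.integer(n_replicates)),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("<supported_tree>", length(x$tree$tip.label), "tips,",
      length(x$support), "supported branches over", x$n_replicates,
      "replicates\n")
  invisible(x)
}

#' Annotate a reference tree with jackknife support
#'
#' Each internal branch of the reference tree receives the percentage of
#' replicate trees containing its bipartition (rounded to one decimal),
#' attached as the internal node label. When rendering with
#' [write_support_newick()], branches below the display threshold appear
#' as `"-"`, the conventional mark for an unsupported branch.
#'
#' @param reference A `phylo` tree.
#' @param replicates List of `phylo` trees on the same leaf set.
#' @return A `supported_tree` whose `support` maps each internal branch of
#'   the reference (by split key) to its percentage.
#' @export
annotate_support <- function(reference, replicates) {
  if (length(replicates) < 1L) stop_("need at least one replicate tree")
  cs <- count_splits(replicates)
  if (!setequal(reference$tip.label, cs$tips) ||
      length(reference$tip.label) != length(cs$tips)) {
    stop_("reference and replicates must share an identical leaf set")
  }
  counts <- cs$counts
  sp <- tree_splits(reference, with_nodes = TRUE)
  pct <- round(100 * as.numeric(
    ifelse(is.na(counts[sp$keys]), 0, counts[sp$keys])) /
      length(replicates), 1)
  names(pct) <- sp$keys
  ntip <- length(reference$tip.label)
  labs <- rep("", reference$Nnode)
  labs[sp$nodes - ntip] <- format_pct(pct)
  tree <- reference
  tree$node.label <- labs
  supported_tree(tree, pct[!duplicated(names(pct))], length(replicates))
}

#' @param x A `supported_tree`.
#' @param path Optional output path.
#' @param display_threshold Supports strictly below this percentage render
#'   as `"-"` (default 50).
#' @rdname annotate_support
#' @export
write_support_newick <- function(x, path = NULL, display_threshold = 50) {
  stopifnot(inherits(x, "supported_tree"))
  tree <- x$tree
  if (!is.null(tree$node.label)) {
    num <- suppressWarnings(as.numeric(tree$node.label))
    low <- !is.na(num) & num < display_threshold
    tree$node.label[low] <- "-"
  }
  to_newick(tree, path)
}
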