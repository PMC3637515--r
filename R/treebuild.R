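#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j}. At each step the pair with the
#' minimal Q joins; exact ties are broken toward the lexicographically
#' smallest pair of cluster representatives (a cluster is represented by its
#' smallest leaf label). Branch lengths follow the usual formulas; negative
#' estimates are clamped to 0 without redistributing the difference. The
#' result is unrooted (trifurcating root node).
#'
#' @param dm Symmetric numeric distance matrix with unique row/column names
#'   (N >= 3), or a `dist` object.
#' @return An [ape::read.tree()]-style `phylo` tree.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 5, 5, 2, 0, 5, 5, 5, 5, 0, 2, 5, 5, 2, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' ape::write.tree(nj_tree(d))
nj_tree <- function(dm) {
  D <- as.matrix(dm)
  n <- nrow(D)
  if (n < 3L) stop_("Neighbor-Joining needs at least 3 taxa")
  ids <- rownames(D) %||% paste0("t", seq_len(n))
  if (anyDuplicated(ids)) stop_("duplicate taxon labels")
  if (max(abs(D - t(D))) > 1e-9) stop_("distance matrix is not symmetric")
  if (any(D < 0)) stop_("distances must be non-negative")
  dimnames(D) <- NULL

  fmt <- function(x) sprintf("%.10g", x)
  node_nwk <- ids     # newick fragment per active node
  node_rep <- ids     # lexicographic representative per active node

  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest sorted representative pair
    key <- vapply(seq_len(nrow(cand)), function(k) {
      paste(sort(c(node_rep[cand[k, 1]], node_rep[cand[k, 2]])),
            collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    f <- pick[1]; g <- pick[2]

    vf <- D[f, g] / 2 + (r[f] - r[g]) / (2 * (n - 2))
    vg <- D[f, g] - vf
    vf <- max(vf, 0); vg <- max(vg, 0)

    du <- (D[f, ] + D[g, ] - D[f, g]) / 2
    keep <- setdiff(seq_len(n), c(f, g))
    newD <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                  c(du[keep], 0))
    new_nwk <- paste0("(", node_nwk[f], ":", fmt(vf), ",",
                      node_nwk[g], ":", fmt(vg), ")")
    new_rep <- min(node_rep[f], node_rep[g])
    node_nwk <- c(node_nwk[keep], new_nwk)
    node_rep <- c(node_rep[keep], new_rep)
    D <- newD
    n <- n - 1L
  }

  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- paste0("(", node_nwk[1], ":", fmt(la), ",",
                node_nwk[2], ":", fmt(lb), ",",
                node_nwk[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

#' Newick serialization
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]: round trips
#' preserve topology, branch lengths (10 significant digits) and labels;
#' unrooted trees are serialized with a trifurcating root.
#'
#' @param tree A `phylo` tree.
#' @param text Newick string.
#' @param path Optional file path (one tree per line on write).
#' @return `to_newick()` returns a Newick string (or writes to `path`);
#'   `from_newick()` returns a `phylo` (or `multiPhylo` if several).
#' @export
to_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname to_newick
#' @export
from_newick <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(path)) ape::read.tree(path) else
    ape::read.tree(text = text)
  if (is.null(tr)) stop_("malformed Newick input")
  tr
}

# Non-trivial bipartitions of an unrooted tree, canonicalized: each split is
# keyed by the sorted tip labels on the side NOT containing the reference
# (alphabetically first) taxon; both sides must have >= 2 tips. Returns a
# character vector of keys (tips joined by "\r"). Optionally also the edge
# child-node each split belongs to.
tree_splits <- function(tree, with_nodes = FALSE) {
  ntip <- length(tree$tip.label)
  tips_all <- sort(tree$tip.label)
  ref <- tips_all[1]
  nnode <- tree$Nnode
  # tip sets per internal node by accumulation over postorder edges
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edges <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- ntip + 1L
  internal <- setdiff(seq_len(nnode) + ntip, root)
  keys <- character(0)
  nodes <- integer(0)
  for (nd in internal) {
    side <- desc[[nd]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(tips_all, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, nd)
  }
  # a rooted binary representation yields the same split from both root
  # children; as a set of splits it must be deduplicated
  if (with_nodes) list(keys = keys, nodes = nodes) else unique(keys)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the non-trivial bipartition
#' sets of two unrooted trees on the same leaf set.
#'
#' @param t1,t2 `phylo` trees with identical tip labels.
#' @return Non-negative integer.
#' @export
#' @examples
#' t1 <- from_newick("((A,B),(C,D));")
#' t2 <- from_newick("((A,C),(B,D));")
#' rf_distance(t1, t2)
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    stop_("trees must share an identical leaf set")
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
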