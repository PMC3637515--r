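#' Simulation settings for synthetic protein families
#'
#' Conditions for the divergent-family generator: a random bifurcating
#' topology (Yule process) with exponential branch lengths, an F81-style
#' 20-state substitution process over the BLOSUM62 background composition,
#' Poisson indels with geometric lengths, and unrelated N-/C-terminal
#' flanks so that full-length queries genuinely exceed their conserved
#' domain. Branch lengths are in expected substitutions per site. When
#' `expected_identity` is set, the tree is rescaled so the mean pairwise
#' path length matches the divergence implied by the closed-form identity
#' curve \eqn{I(t) = e^{-t} + (1 - e^{-t}) \sum_a \pi_a^2}.
#'
#' @param n_leaves Number of leaves (>= 4).
#' @param root_length Ancestral domain length in residues (>= 20).
#' @param indel_rate Indel events per site per unit branch length.
#' @param indel_mean_length Mean indel tract length (geometric).
#' @param branch_mean Mean branch length.
#' @param branch_dist Branch-length distribution: `"uniform"` (default;
#'   uniform on `[0.5, 1.5] * branch_mean`, bounded away from zero so the
#'   generating topology stays identifiable from finite sequence) or
#'   `"exponential"`.
#' @param flank_length Length of each unrelated terminal flank.
#' @param expected_identity Optional target mean pairwise identity in
#'   `(0, 1)`; rescales the tree depth accordingly.
#' @param rng_seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_leaves = 12L, root_length = 250L, indel_rate = 0.01,
                       indel_mean_length = 3, branch_mean = 0.2,
                       branch_dist = c("uniform", "exponential"),
                       flank_length = 30L, expected_identity = NULL,
                       rng_seed = NULL) {
  branch_dist <- match.arg(branch_dist)
  if (n_leaves < 4L) stop_("n_leaves must be >= 4")
  if (root_length < 20L) stop_("root_length must be >= 20")
  if (indel_rate < 0 || branch_mean <= 0 || indel_mean_length < 1) {
    stop_("rates must be non-negative, branch_mean positive, ",
          "indel_mean_length >= 1")
  }
  structure(list(n_leaves = as.integer(n_leaves),
                 root_length = as.integer(root_length),
                 indel_rate = indel_rate,
                 indel_mean_length = indel_mean_length,
                 branch_mean = branch_mean,
                 branch_dist = branch_dist,
                 flank_length = as.integer(flank_length),
                 expected_identity = expected_identity,
                 rng_seed = rng_seed),
            class = "sim_config")
}

#' Expected pairwise identity under the substitution model
#'
#' Closed form for two sequences separated by total path length `t` (no
#' indels): a site is identical if unsubstituted on the whole path
#' (probability \eqn{e^{-t}}) or resampled to a coincidentally equal
#' residue, giving \eqn{I(t) = e^{-t} + (1 - e^{-t}) \sum_a \pi_a^2}.
#'
#' @param t Total path length (expected substitutions per site).
#' @param background Residue frequencies (default BLOSUM62 composition).
#' @return Expected identity fraction in `(0, 1]`.
#' @export
expected_pairwise_identity <- function(t, background = BLOSUM62_BACKGROUND) {
  cc <- sum(background^2)
  exp(-t) + (1 - exp(-t)) * cc
}

# Inverse of expected_pairwise_identity.
path_length_for_identity <- function(identity,
                                     background = BLOSUM62_BACKGROUND) {
  cc <- sum(background^2)
  if (identity <= cc || identity > 1) {
    stop_("expected_identity must be in (", round(cc, 3), ", 1]")
  }
  -log((identity - cc) / (1 - cc))
}

#' Random bifurcating tree (Yule process)
#'
#' Grows a topology by repeatedly splitting a uniformly chosen extant
#' lineage, draws i.i.d. branch lengths, and assigns leaf labels `t1..tn`
#' in random order.
#'
#' @param n_leaves Number of leaves (>= 4).
#' @param branch_mean Mean branch length.
#' @param branch_dist `"uniform"` (on `[0.5, 1.5] * branch_mean`) or
#'   `"exponential"`; see [sim_config()].
#' @param rng_seed Optional integer seed.
#' @return A rooted binary `phylo` tree with branch lengths.
#' @export
sample_tree <- function(n_leaves, branch_mean = 0.2,
                        branch_dist = c("uniform", "exponential"),
                        rng_seed = NULL) {
  if (n_leaves < 4L) stop_("n_leaves must be >= 4")
  branch_dist <- match.arg(branch_dist)
  rlen <- if (branch_dist == "uniform") {
    function() stats::runif(1, 0.5 * branch_mean, 1.5 * branch_mean)
  } else {
    function() stats::rexp(1, 1 / branch_mean)
  }
  with_rng_seed(rng_seed, {
    # nested-list topology; each element is either a tip placeholder or a
    # pair of subtrees
    grow <- function(node, path) {
      if (length(path) == 0L) return(list("tip", "tip"))
      node[[path[1]]] <- grow(node[[path[1]]], path[-1])
      node
    }
    count_tips <- function(node) {
      if (identical(node, "tip")) return(1L)
      count_tips(node[[1]]) + count_tips(node[[2]])
    }
    topo <- list("tip", "tip")
    for (k in seq_len(n_leaves - 2L)) {
      # walk to a uniformly random tip
      path <- integer(0)
      node <- topo
      while (!identical(node, "tip")) {
        n1 <- count_tips(node[[1]])
        n2 <- count_tips(node[[2]])
        step <- if (stats::runif(1) < n1 / (n1 + n2)) 1L else 2L
        path <- c(path, step)
        node <- node[[step]]
      }
      topo <- grow(topo, path)
    }
    labels <- sample(paste0("t", seq_len(n_leaves)))
    idx <- 0L
    nwk <- function(node) {
      if (identical(node, "tip")) {
        idx <<- idx + 1L
        lab <- labels[idx]
      } else {
        lab <- paste0("(", nwk(node[[1]]), ",", nwk(node[[2]]), ")")
      }
      paste0(lab, ":", sprintf("%.10g", rlen()))
    }
    body <- paste0("(", nwk(topo[[1]]), ",", nwk(topo[[2]]), ");")
    ape::read.tree(text = body)
  })
}

#' Evolve a protein family along a tree
#'
#' The root domain is drawn i.i.d. from the background composition. Along
#' each branch of length `t`, every site substitutes with probability
#' `1 - exp(-t)` to a residue drawn from the background (F81 style, so a
#' substitution may resample the same residue), and indel events arrive as
#' Poisson(`indel_rate * t * length`) with geometric tract lengths,
#' insertion or deletion with equal probability at a uniform position.
#' Site-origin ids are tracked through all events, so realized pairwise
#' identity is measured over truly homologous site pairs. Each leaf's
#' domain is framed by unrelated flanks drawn i.i.d. from the background,
#' and the ground-truth domain boundaries (0-based half-open, on the
#' full-length record) are recorded.
#'
#' @param tree A rooted `phylo` with branch lengths (e.g. [sample_tree()]).
#' @param config A [sim_config()].
#' @param rng_seed Optional integer seed (overrides the config's).
#' @return A `simulated_family`: `true_tree`, `records` (full-length
#'   [seq_record()]s), `boundaries` (data frame `id`, `start`, `end`),
#'   `domains` (core residue strings), `mean_identity` (realized average
#'   pairwise identity over shared homologous sites), `config`.
#' @export
evolve_sequences <- function(tree, config = sim_config(), rng_seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  bg <- unname(BLOSUM62_BACKGROUND)
  seed <- rng_seed %||% config$rng_seed
  with_rng_seed(seed, {
    ntip <- length(tree$tip.label)
    L0 <- config$root_length
    root_state <- list(res = sample.int(20L, L0, replace = TRUE, prob = bg),
                       ids = seq_len(L0))
    next_id <- L0 + 1L

    evolve_branch <- function(state, t) {
      res <- state$res; ids <- state$ids
      len <- length(res)
      if (len > 0L && t > 0) {
        p_sub <- 1 - exp(-t)
        hit <- which(stats::runif(len) < p_sub)
        if (length(hit)) {
          res[hit] <- sample.int(20L, length(hit), replace = TRUE, prob = bg)
        }
        n_events <- stats::rpois(1, config$indel_rate * t * len)
        for (e in seq_len(n_events)) {
          len <- length(res)
          if (len == 0L) break
          tract <- stats::rgeom(1, 1 / config$indel_mean_length) + 1L
          if (stats::runif(1) < 0.5) {           # insertion
            pos <- sample.int(len + 1L, 1L) - 1L # insert after pos
            ins <- sample.int(20L, tract, replace = TRUE, prob = bg)
            res <- append(res, ins, after = pos)
            ids <- append(ids, seq.int(next_id, length.out = tract),
                          after = pos)
            next_id <<- next_id + tract
          } else {                                # deletion
            pos <- sample.int(len, 1L)
            drop <- pos:min(pos + tract - 1L, len)
            res <- res[-drop]
            ids <- ids[-drop]
          }
        }
      }
      list(res = res, ids = ids)
    }

    children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    leaf_state <- vector("list", ntip)
    recurse <- function(node, state) {
      for (k in children[[as.character(node)]]) {
        child <- tree$edge[k, 2]
        st <- evolve_branch(state, tree$edge.length[k])
        if (child <= ntip) leaf_state[[child]] <<- st
        else recurse(child, st)
      }
    }
    recurse(ntip + 1L, root_state)

    # realized identity over shared homologous sites, averaged over pairs
    pair_identity <- function(a, b) {
      shared <- intersect(a$ids, b$ids)
      if (!length(shared)) return(NA_real_)
      mean(a$res[match(shared, a$ids)] == b$res[match(shared, b$ids)])
    }
    idents <- c()
    for (i in seq_len(ntip - 1L)) {
      for (j in (i + 1L):ntip) {
        idents <- c(idents, pair_identity(leaf_state[[i]], leaf_state[[j]]))
      }
    }
    mean_identity <- mean(idents, na.rm = TRUE)
    if (mean_identity < 0.05) {
      warning("realized mean pairwise identity below 5%; ",
              "sequences are near-random", call. = FALSE)
    }

    fl <- config$flank_length
    records <- vector("list", ntip)
    boundaries <- data.frame(id = character(ntip), start = integer(ntip),
                             end = integer(ntip))
    domains <- character(ntip)
    for (i in seq_len(ntip)) {
      core <- decode_residues(leaf_state[[i]]$res - 1L)
      nflank <- function(k) decode_residues(
        sample.int(20L, k, replace = TRUE, prob = bg) - 1L)
      left <- if (fl > 0L) nflank(fl) else ""
      right <- if (fl > 0L) nflank(fl) else ""
      id <- tree$tip.label[i]
      records[[i]] <- seq_record(id, paste0(left, core, right))
      boundaries[i, ] <- list(id, fl, fl + nchar(core))
      domains[i] <- core
    }
    structure(list(true_tree = tree, records = records,
                   boundaries = boundaries, domains = domains,
                   mean_identity = mean_identity, config = config),
              class = "simulated_family")
  })
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf("<simulated_family> %d leaves, domain ~%d aa, mean pairwise identity %.1f%%\n",
              length(x$records), x$config$root_length,
              100 * x$mean_identity))
  invisible(x)
}

#' Simulate a complete family (tree + sequences)
#'
#' Samples a Yule tree under the config (rescaled to the requested
#' `expected_identity` when set) and evolves sequences along it.
#'
#' @param config A [sim_config()].
#' @param rng_seed Optional integer seed (overrides the config's).
#' @return A `simulated_family` (see [evolve_sequences()]).
#' @export
simulate_family <- function(config = sim_config(), rng_seed = NULL) {
  seed <- rng_seed %||% config$rng_seed
  seeds <- derive_seeds(seed, 2L)
  tree <- sample_tree(config$n_leaves, config$branch_mean,
                      branch_dist = config$branch_dist %||% "uniform",
                      rng_seed = seeds[[1]])
  if (!is.null(config$expected_identity)) {
    target <- path_length_for_identity(config$expected_identity)
    paths <- stats::cophenetic(tree)
    tree$edge.length <- tree$edge.length *
      target / mean(paths[upper.tri(paths)])
  }
  evolve_sequences(tree, config, rng_seed = seeds[[2]])
}

#' Write a simulated family's artifacts
#'
#' FASTA of full-length leaves, TSV domain boundaries, Newick true tree and
#' a JSON echo of the configuration plus realized identity.
#'
#' @param family A `simulated_family`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "simulated_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(family$records, file.path(dir, "leaves.fasta"))
  write_boundary_table(family$boundaries, file.path(dir, "boundaries.tsv"))
  to_newick(family$true_tree, file.path(dir, "true_tree.nwk"))
  cfg <- family$config
  cfg$mean_identity <- family$mean_identity
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
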