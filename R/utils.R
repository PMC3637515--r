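#' @useDynLib pssmphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical amino-acid order used throughout (BLOSUM row order).
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Background amino-acid frequencies: the marginal composition underlying
# BLOSUM62 (Henikoff & Henikoff). Sums to 1 exactly.
BLOSUM62_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
  Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
  L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
  S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)

.pkg_cache <- new.env(parent = emptyenv())

# 20x20 BLOSUM62 in half-bit units, AA_ORDER on both axes.
blosum62_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- unname(e$BLOSUM62[AA_ORDER, AA_ORDER])
  }
  .pkg_cache$blosum62
}

# P(a | b): conditional substitution probabilities implied by BLOSUM62
# half-bit scores, s_ab = 2 log2(q_ab / (p_a p_b)) so
# P(a|b) = q_ab / p_b = p_a 2^(s_ab / 2); rows renormalized to absorb the
# integer rounding of the published matrix. Column b indexes the observed
# residue, row entries give the pseudocount mass on residue a.
blosum62_conditional <- function() {
  if (is.null(.pkg_cache$cond)) {
    s <- blosum62_matrix()
    p <- unname(BLOSUM62_BACKGROUND)
    cond <- p * 2^(s / 2)              # cond[a, b], recycling p down columns
    cond <- sweep(cond, 2, colSums(cond), "/")
    .pkg_cache$cond <- cond
  }
  .pkg_cache$cond
}

# Integer-code a residue string for the C++ aligner: 0..19 in AA_ORDER,
# 20 for X. Stops on anything else.
encode_residues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  codes <- match(chars, c(AA_ORDER, "X")) - 1L
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("illegal residue '", chars[bad], "' at position ", bad, call. = FALSE)
  }
  codes
}

decode_residues <- function(codes) {
  paste(c(AA_ORDER, "X")[codes + 1L], collapse = "")
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed uses the current stream as-is.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one seed (replicate loops); keeps
# values in the 32-bit range R accepts.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep_len(list(NULL), n))
  with_rng_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
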