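---
title: "Alignment-free phylogenetics from profile composite scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free phylogenetics from profile composite scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmphylo)
```

## The method

`pssmphylo` infers phylogenies for highly divergent protein families —
families such as the recA/RAD51 recombinases, whose paralogous subgroups sit
near 30% average pairwise identity, where multiple sequence alignment
becomes unreliable — without ever building a multiple alignment. The
pipeline:

1. **Profile library.** Each family member contributes the conserved domain
   region of its sequence (boundaries are an input, e.g. from a CDD-style
   domain scan) as the seed of a position-specific scoring matrix (PSSM).
   Seeds are enriched against a target database of putative homologs:
   sequences whose local-alignment E-value against the current profile
   passes an inclusion threshold are stacked onto the seed's columns, and
   the profile is rebuilt from weighted residue frequencies with
   substitution-matrix pseudocounts.
2. **Composite scoring.** Every full-length query is locally aligned
   (affine-gap Smith–Waterman) against every profile. A comparison is
   summarized by its *composite score*: percent identity (relative to the
   profile's seed, gap columns counted in the denominator) times percent
   coverage (fraction of profile columns in the alignment). The composite
   ranges over [0, 10000]; its log10 display scale runs from 0 to 4, with 4
   attained exactly by a perfect full-length self-alignment.
3. **Distances and tree.** The N×M composite matrix — after per-query
   retention of the top-scoring 75% of profiles, the report-limit rule —
   yields an N×N Euclidean distance matrix, from which a Neighbor-Joining
   tree is inferred. Unit scaling of distances (0–1) is applied only for
   display.
4. **Support.** Branch stability is assessed by jackknife: each replicate
   subsamples 80% of the matrix columns without replacement, rebuilds
   distances, and reruns NJ; replicate trees are summarized by strict
   majority-rule consensus, and supports are appended to branches of the
   full-data tree ("-" marks a branch below the display threshold).
5. **Signal-to-noise.** The Difference Ratio (DR) quantifies, per
   query–profile coordinate, how far the observed composite score stands
   above chance: each of (by default) 100 replicates shuffles every query's
   residue order and rescoring yields a null distribution per coordinate;
   `DR = (composite_wt − mean_random) / SD_random`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `evalue_threshold` | 7e-13 | Profile inclusion threshold; suited to a small dedicated target database (E-values scale with database size — against a large non-redundant database 1e-6 is the comparable setting). |
| `iterations` | 3 | Search-and-rebuild rounds of profile enrichment. |
| `pseudocount_weight` | 10 | Prior weight β mixed against the effective observation count α (mean distinct residues per column − 1). |
| `gap_open`, `gap_extend` | 11, 1 | Affine gap costs in half-bit units, the standard protein-search setting; scores are half-bit log-odds against the BLOSUM62 background composition. |
| `b_fraction` | 0.75 | Per-query retention: top `ceil(0.75 M)` profiles kept, remaining cells stored as 0. |
| jackknife `fraction`, `n_replicates` | 0.8, 5000 | Column subsample per replicate and replicate count (interactive work and the test suite use far fewer replicates; supports converge quickly at desk scale). |
| DR `n_replicates` | 100 | Shuffle replicates per query. |

Where the method's published description is silent — sequence weighting,
pseudocount form, gap costs, log-odds units — the package adopts the
standard PSI-BLAST-family conventions (Henikoff position-based weights,
substitution-matrix conditional pseudocounts, half-bits, 11/1). These are
declared defaults, not inferences.

## Decisions taken where the design was open

* **Identity reference.** Percent identity is measured against the
  profile's stored seed sequence; coverage is relative to profile length
  `L`, not query length — full-length queries are scored for how much of
  the conserved domain they match. A `coverage_ref`-style switch was
  considered and rejected: the 0–10000 composite range (log scale 0–4) is
  only attained with profile-length coverage.
* **Boundary convention.** Domain-boundary tables are 0-based, half-open
  (`id`, `start`, `end`), stated in the file header comment.
* **Masked cells.** Cells dropped by retention enter the Euclidean sum as
  zeros (the matrix is dense); an alternative drop-from-the-sum mode was
  considered and rejected for the same density reason.
* **E-values.** Profile inclusion uses an empirical calibration: Gumbel
  parameters fitted by the method of moments to maximal local-alignment
  scores of residue-shuffled database decoys, `E(s) = n_db (1 −
  exp(−exp(−λ(s−μ))))`. This is a native component of the package, honest
  by construction (a fresh-decoy check holds P(E ≤ 0.01) ≈ 0.01), and the
  familiar threshold values keep their conventional meaning relative to
  database size.
* **NJ determinism.** Q-criterion ties break toward the lexicographically
  smallest pair of cluster representatives; negative branch-length
  estimates are clamped to 0 without redistribution. Both choices are for
  reproducibility; they do not affect additive inputs.
* **Jackknife unit.** "Data points" are resampled as whole profile columns
  (the M dimension), so every replicate is a coherent distance
  recomputation; cell-wise deletion would leave pair distances undefined.
* **Consensus rule.** Strict majority (> 50%), without greedy extension.
* **DR details.** One shuffle per query per replicate; the SD uses the
  population (n) divisor (configurable); coordinates with zero null SD get
  DR 0 when signal equals the null mean and a sentinel cap (1e4) otherwise;
  retention is never applied inside the randomization scoring. Replicate
  moments use Welford streaming updates so shuffle fixed points (e.g.
  homopolymers) give an exact zero SD.

## The synthetic family generator

The simulator provides what real data cannot: families with a known true
tree at controlled divergence. A Yule topology is grown by uniform lineage
splitting; branch lengths are i.i.d. uniform on `[0.5, 1.5] ×
branch_mean`. The root domain (default 250 residues, the scale of a
recA-like core domain) is drawn from the BLOSUM62 background composition;
along each branch of length *t* (expected substitutions per site) every
site substitutes with probability `1 − exp(−t)` to a background draw (an
F81-style 20-state model), and indel events arrive as Poisson with
geometric tract lengths. Unrelated flanks (default 30 residues per side)
frame each leaf domain so that full-length queries genuinely exceed their
domain and the coverage statistic is exercised. Site-origin ids are tracked
through all events, so realized pairwise identity is measured over truly
homologous positions.

The F81 choice is deliberate: it admits the closed form
`I(t) = exp(−t) + (1 − exp(−t)) Σ πa²`, which both calibrates the generator
(a requested expected identity is hit by rescaling the tree's mean pairwise
path length) and is itself verified by simulation in the test suite.

Two generator choices deserve justification:

* **Branch lengths bounded away from zero.** With exponential branch
  lengths, a sizable fraction of random trees contain internal edges of
  effectively zero length, and their topology is unidentifiable from
  finite sequences by *any* method (verified against an independent
  alignment-based NJ oracle). Benchmark families therefore use the uniform
  distribution above; the exponential remains available
  (`branch_dist = "exponential"`).
* **What the simulator does not model.** Among-site rate variation,
  compositional drift, domain shuffling or fusion, and site-specific
  constraint are absent. Passing recovery tests on these families shows the
  pipeline correctly converts divergence into tree signal under a neutral,
  homogeneous model; it does not certify performance on real families
  whose divergence is structured.

## The end-to-end benchmark

The headline property is full-pipeline recovery: simulate a 12-leaf family
at within-group-like conservation (expected pairwise identity ≈ 55%, the
middle of the 44–75% range typical of recombinase subfamilies), run
extraction → profile building → composite scoring → Euclidean distances →
NJ, and compare the result to the generating tree; recovery (RF = 0) is
expected in at least 80% of seeded runs, and mean RF must increase as
divergence is pushed through the ~30% between-group regime toward <10%
identity.

One configuration note: the benchmark scores the composite matrix with
`b_fraction = 1`. The top-75% retention rule earns its keep on large
multi-family libraries, where a query's bottom quartile of profiles is
cross-family noise; in a single 12-member family with one profile per
member, every column carries homologous signal, and masking a quarter of
them deletes signal rather than noise (recovery drops from ~90% to ~40% of
runs). The retention rule itself is tested separately at library scale
(exactly 75 of 100 profiles retained per query).

Problem sizes used by the test suite — 12-leaf families, 250-residue
domains, 20 recovery runs, 100-replicate DR and reduced jackknife replicate
counts — are the package's chosen desk-scale study conditions; all method
defaults (75% retention, 80%/5000 jackknife, 100 DR replicates, 3 profile
iterations) keep their standard values.

## Numerical choices and degenerate inputs

* Alignment tie-breaking: the first maximal cell in row-major scan;
  traceback prefers ending the alignment, then the diagonal — yielding the
  shortest, most upstream optimal alignment. Zero-score queries return the
  empty alignment with composite 0.
* `log_scale(x) = log10(max(x, 1))` so the empty alignment maps to 0.
* Composite ties at the retention boundary keep the smaller profile index.
* Gumbel calibration refuses zero-variance decoy scores (e.g. homopolymer
  databases) rather than emitting meaningless E-values.
* Distance matrices must be symmetric within 1e-9 and non-negative; NJ
  requires N ≥ 3; jackknife requires at least 2 columns per replicate.
* All stochastic steps (decoy shuffles, jackknife, DR, simulation) are
  deterministic given their `rng_seed`, with child seeds derived for
  replicate streams; the caller's RNG state is never disturbed.

## Known limitations

* Identity-to-seed saturates with divergence; below ~10% identity the
  composite carries little rank information and trees degrade (this is by
  design the regime the degradation test probes).
* E-value calibration extrapolates a moment-fitted Gumbel far into its
  tail for thresholds like 7e-13; inclusion decisions near the threshold
  are approximate. At desk scale homologs and decoys are separated by
  hundreds of half-bits, so decisions are insensitive to this.
* Exact Smith–Waterman throughout (no heuristic seeding): library sizes
  are desk-scale; scoring 545-sequence problems is feasible but slow in a
  single thread.
* The consensus builder assumes replicate trees on an identical leaf set;
  partial-overlap consensus is out of scope.
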