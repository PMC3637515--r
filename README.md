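# pssmphylo

Alignment-free phylogenetic inference for highly divergent protein
families, from profile composite scores.

## The problem

Deep phylogenies of ancient protein families — the recA/RAD51 recombinase
superfamily is the canonical case — are hard because paralogous subgroups
sit near 30% average pairwise identity, where multiple sequence alignments
of full-length sequences become unreliable and alignment-based trees lose
deep-branch support. `pssmphylo` implements a profile-based alternative:
instead of one multiple alignment, each family member's conserved domain
seeds a position-specific scoring matrix (PSSM), every full-length sequence
is locally aligned against every profile, and each comparison is reduced to
a **composite score**

    composite = percent identity × percent coverage  ∈ [0, 10000]

(identity to the profile's seed, gap columns counted; coverage relative to
profile length; log10 display scale 0–4). The N×M composite matrix, after
per-query retention of the top-scoring 75% of profiles, yields an N×N
Euclidean distance matrix, and a Neighbor-Joining tree is inferred from it.
Branch stability comes from jackknife resampling (80% of matrix columns,
majority-rule consensus over replicates), and per-coordinate
signal-to-noise from a randomization statistic, the **Difference Ratio**

    DR = (composite_wt − mean composite_random) / SD_random

over residue-shuffled copies of each query (100 replicates by default).

The package is aimed at molecular evolution researchers who need distance
trees for families too divergent to align, and at methodologists who want
every stage of such a pipeline testable: a synthetic family simulator
(substitutions + indels along a random tree, unrelated terminal flanks,
known true topology) makes end-to-end accuracy measurable at desk scale.

## Worked example

Simulate a 12-member family at ~55% mean pairwise identity, run the whole
pipeline, and compare the inferred tree with the truth:

```r
library(pssmphylo)

fam <- simulate_family(sim_config(n_leaves = 12, expected_identity = 0.55,
                                  rng_seed = 1))
fam
#> <simulated_family> 12 leaves, domain ~250 aa, mean pairwise identity 55.3%

domains <- extract_domains(fam$records, fam$boundaries)
lib <- build_pssm_library(domains, fam$records, iterations = 1,
                          n_decoys = 40, rng_seed = 2)

# a perfect self-comparison attains the top of the 0-4 log scale
self <- align_query_to_pssm(fam$records[[1]], lib$pssms[[1]])
log_scale(self$composite)
#> [1] 4

cm <- build_composite_matrix(fam$records, lib, b_fraction = 1.0)
tree <- nj_tree(euclidean_distances(cm))
rf_distance(tree, fam$true_tree)
#> [1] 0

# jackknife support on the inferred tree
reps <- jackknife_replicates(cm, fraction = 0.8, n_replicates = 100,
                             rng_seed = 3)
supported <- annotate_support(tree, reps)
range(supported$support)
#> [1] 100 100
```

`rf_distance` of 0 means the inferred topology equals the generating tree;
the self-alignment hits the maximal log score of 4 (identity 100 ×
coverage 100), and at this conservation level every branch of the inferred
tree is present in all 100 jackknife replicates. Support values are
percentages of replicates containing each branch; "-" in rendered Newick
marks branches below 50.

A thin command-line wrapper exposes the same steps
(`exec/pssmphylo simulate|build-pssms|score|dist|tree|jackknife|dr|rf`,
with `--seed` and `--out`).

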