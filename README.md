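# circanet

Detecting 24-hour rhythmic genes in replicated RNA-seq time courses and
testing whether their peak phases are organized along a gene interaction
network.

Bulk RNA-seq time courses of a circadian tissue — flies or mice sampled
every 2 h over two days, in two independent experiments and two ambient
conditions — pose two linked questions. First, **which genes cycle**, and at
what phase? Second, do cycling genes behave as isolated oscillators, or do
genes that interact (as recorded in a curated network such as a pathway
database export) **peak at similar times**, i.e. is the phase pattern
organized on the network? `circanet` answers both with transparent, testable
statistics, and ships a synthetic-data generator with planted ground truth so
that every stage can be calibrated and power-tested without external data.

## The statistics at the core

**Cycling detection.** For each gene, harmonic (cosinor) regression at fixed
period T = 24 h:

    y(t) = M + A·cos(2π(t − φ)/T) + ε

fit by OLS on `[1, cos(2πt/T), sin(2πt/T)]`; the evidence for cycling is the
F test of the two harmonic coefficients jointly zero (p from F(2, n−3));
amplitude A = √(β_cos² + β_sin²) and peak phase φ = (T/2π)·atan2(β_sin,
β_cos) mod T. A gene is **called cycling** when p < 0.1 in *both* independent
experiments and the two phase estimates agree to within Δφ < 3 h on the
circle. Replication is the error control: under the null the expected number
of chance calls is

    E[chance] = N · p_thresh² · (Δφ_max / 12)

e.g. 6774 genes × 0.1² × 3/12 ≈ 17.

**Phase statistics.** Circular means, the Jammalamadaka–SenGupta circular
correlation, von Mises kernel density peaks, KS comparisons of phase
distributions (with an explicit, reported cut point), and paired signed
phase shifts between conditions (positive = phase advance in the colder
condition).

**Network phase organization.** Cycling genes are mapped onto the largest
connected component of the network; for every cycling-gene pair at geodesic
(BFS hop) distance d the circular phase difference Δφ is computed, and the
per-distance median Δφ profile is compared to a null built by re-placing the
cycling genes uniformly at random on the network (5000 permutations by
default, phases carried along as a multiset). The one-sided empirical
p-value per distance class uses the add-one estimator
`(1 + #{null ≤ obs}) / (1 + n_perm)`, and an OLS trend of median Δφ on d
summarizes whether phase similarity decays with network distance.

## Worked example

Simulate a study whose cold-condition phases are planted to be organized on
the network, then detect the cyclers and test for organization:

```r
library(circanet)

net    <- generate_network(300, 8, "erdos_renyi", seed = 42)
design <- sim_design(noise_cv = 0.1, phase_jitter_sd = 0.5, seed = 42)

truth_18 <- plant_phases(net, frac_cycling = 0.25, coupling = 0.9,
                         n_smooth = 20, seed = 1, condition = "18C")
mats <- simulate_experiment(truth_18, design)   # V1_18C and V2_18C matrices

calls <- call_cycling(fit_harmonic_matrix(mats$V1_18C),
                      fit_harmonic_matrix(mats$V2_18C))
sum(calls$is_cycling)                           # 75 of 75 planted cyclers

lcc    <- largest_connected_component(net)
phases <- setNames(calls$consensus_phase[calls$is_cycling],
                   calls$gene_id[calls$is_cycling])
phases <- phases[names(phases) %in% igraph::V(lcc)$name]
permutation_null(lcc, phases, n_perm = 1000, seed = 7, min_pairs = 20)
```

```
Network phase organization: 75 cycling genes, 1000 permutations (alternative: less )
 d n_pairs median_dphi empirical_p null_q025 null_q50 null_q975 n_perm_valid
 1      88   0.4764187 0.000999001 0.9840067 1.367455  1.747528         1000
 2     529   1.0528087 0.000999001 1.1831071 1.355888  1.493631         1000
 3    1600   1.4286009 0.999000999 1.3020175 1.352790  1.397510         1000
 4     550   1.5496856 0.969030969 1.1591549 1.355263  1.567607         1000
trend: slope 0.360 h/hop, p = 0.0379 (4 classes)
```

Read: immediate network neighbours (d = 1) have a median phase difference of
0.48 h where random placement predicts ~1.37 h — none of the 1000 null
medians was as small (p = 1/1001) — and the median difference rises with
distance (slope 0.36 h per hop). That is the signature of phase organization
on the network. (Classes d ≥ 3 sit *above* their null here because planting
synchronizes clusters, which pushes the remaining dissimilarity outward —
one-sided "smaller than null" p-values near 1 are expected there.)

`run_pipeline()` drives the whole analysis (filter → fit → call → phase →
network) from TSV matrices, metadata and an edge list on disk, writing TSV
and JSON outputs plus a run manifest; `inst/cli/circanet.R` is a thin
command-line wrapper with `simulate`, `filter`, `detect`, `phases`,
`network-test` and `run` subcommands.

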