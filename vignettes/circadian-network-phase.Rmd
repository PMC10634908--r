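---
title: "Circadian cycling detection and network phase organization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian cycling detection and network phase organization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circanet)
```

# The problem

A circadian tissue sampled by bulk RNA-seq every 2 h across a stable
two-day window yields, per gene, a short noisy time series. Two questions
drive the package. First, which genes oscillate with a 24 h period, and at
what Zeitgeber-time (ZT) phase do they peak? Second, given a curated
gene-interaction network, do interacting genes peak at similar times — is
the phase pattern *organized* on the network, as one would expect if the
regulatory network itself propagates timing information?

The design the package targets has two independent experiments (`V1`, `V2`;
different sequencing batches or even technologies) and two conditions (for
instance ambient temperatures `18C` and `25C`). Replication across
experiments, not multiple-testing correction, is the false-discovery
control, and everything downstream works with phases estimated per
condition by combining both experiments.

# Cycling detection

## Model

For each gene, ordinary least squares of expression on
$[1, \cos(2\pi t/T), \sin(2\pi t/T)]$ with the period fixed at $T = 24$ h —
a single first harmonic, no period scan. This is deliberate: with ~24
samples over two cycles, a fixed-period cosinor has well-understood
calibration, and the two-experiment replication criterion supplies
robustness that a more flexible model would have to buy with degrees of
freedom. Evidence of cycling is the F statistic of the two harmonic
coefficients jointly zero, $p$ from $F(2, n-3)$. The peak phase is
$\hat\phi = (T/2\pi)\,\mathrm{atan2}(\hat\beta_s, \hat\beta_c) \bmod T$ and
the amplitude $\hat A = \sqrt{\hat\beta_c^2 + \hat\beta_s^2}$ (half
peak-to-trough). Replicates enter as independent observations. Fits are on
raw TPM by default; `log_transform` switches to $\log_2(\mathrm{TPM}+1)$
for users who prefer variance stabilisation — the choice is exposed rather
than hidden because phase estimates are nearly invariant to it but p-values
are not.

Two conventions keep the pipeline total on degenerate input: an exactly
constant series reports amplitude 0, p = 1, phase `NA`; a design whose
times coincide modulo the period is an error, not a silent near-singular
solve (the guard is a reciprocal-condition check at $10^{-12}$).

## The dual-experiment call and its chance expectation

A gene is called cycling in a condition when $p < 0.1$ in both experiments
and the two phase estimates differ by less than 3 h on the circle. Both
inequalities are strict. Under a global null the two p-values are
independent uniforms and the phase difference is uniform on $[0, 12]$ h, so
the expected number of chance calls among $N$ genes is
$N \cdot p_{\mathrm{thresh}}^2 \cdot (\Delta\phi_{\max}/12)$ —
`expected_chance_cyclers()`. For a 6774-gene universe at the default
thresholds this is 16.935 ≈ 17 genes; `chance_fdr_summary()` expresses it
as a percentage of the observed number of calls. The test suite verifies
the formula empirically: across 200 simulated null datasets of flat
lognormal-noise genes, the mean number of calls sits within three binomial
standard errors of the closed form.

## Phase differences on the circle

All phase comparisons use the circular distance
$\min(|\Delta| \bmod 24,\; 24 - |\Delta| \bmod 24) \in [0, 12]$ h. A
published formulation of this quantity as $\min(\theta_1, \theta_2)$ with
$\theta_2 = \phi_1 + 2\pi - \phi_2$ is internally inconsistent when
$\phi_1 > \phi_2$ (the second arc exceeds $2\pi$); the standard circular
distance is what the $[0,12]$ h range and the chance calculation above
imply, and is what the package implements, cross-checked in the tests
against a brute-force wrap search.

# Phase-distribution analyses

Consensus phases per condition are circular means of the two experiments'
estimates (undefined — flagged `NA` — if the two are exactly antipodal).
Between-condition comparisons use a two-sample KS test after cutting the
circle at a configurable point (default ZT0, lights-on). The cut matters:
the KS statistic is equivariant only under joint rotation of both samples
and the cut, so the cut is always reported with the result rather than
hidden.

Density peaks use a von Mises kernel on a 0.1 h grid. The default
concentration $\kappa = 8$ (circular SD ≈ 1.4 h) resolves modes ≥ 4 h
apart, the scale of biologically distinct morning/evening clusters. A peak
must be a strict local maximum on the circular grid *and* exceed 1.2× the
mean density; with a few hundred phases this keeps uniform data quiet while
recovering planted unimodal and bimodal configurations to within 0.5 h
(both properties are in the test suite; at samples much below ~1000 the
KDE's relative fluctuation grows like $n^{-1/2}$ and spurious low-contrast
peaks can pass the default threshold).

Paired per-gene analyses between conditions: signed phase shift wrapped
into $(-12, 12]$ h with positive = advance in the first (colder) condition;
two-tailed Wilcoxon signed-rank tests on per-gene expression variances (all
genes — variance is noise-dominated because most genes are flat) and on
fitted amplitudes of common cyclers. Variance comparisons are run per
experiment; combining experiments first can let one batch dominate, so both
views are exposed and the pipeline reports per-experiment results.

# Network phase organization

The interaction network arrives as a plain two-column edge list (exported
from a pathway database upstream; a small synthetic fixture ships with the
package). It is simplified (self-loops and duplicate edges dropped, with
counts) and reduced to its largest connected component — distances are only
meaningful within a component, and in database-derived graphs the LCC holds
the large majority of nodes. Ties between equal-size components are broken
toward the component containing the lexicographically smallest gene ID so
the reduction is deterministic.

Three preliminary checks guard the main test:

* **Representativeness** — KS comparison of the phases of on-network
  cyclers against all cyclers; a skewed subset would confound any network
  effect.
* **Degree** — KS comparison of cycling-gene degrees against all degrees,
  asking whether connectivity predicts rhythmicity. (No specific test is
  canonical here; KS was chosen for consistency and documented.)
* **Localization** — one-sided Wilcoxon rank-sum of within-subset pairwise
  geodesic distances against all-pairs distances. All-pairs distances are
  computed exactly by BFS from every node; above a configurable ceiling
  (default $10^7$ pairs) a seeded uniform subsample is used and flagged in
  the result.

The main statistic is the **distance–phase profile**: for every unordered
pair of cycling genes at geodesic distance $d$, the circular phase
difference; per class, the median. Classes need at least `min_pairs`
(default 50) pairs — medians of sparse classes are unstable and would
otherwise dominate the trend — and by default the profile stops at the
largest distance still meeting that minimum. A linear OLS trend of the
per-class medians on $d$ (one unweighted point per class, matching how the
profile is summarised visually) gives a slope in hours per hop; an exactly
flat profile reports slope 0 with p = 1 by convention, an exact non-flat
line p = 0.

The null model re-places the cycling genes: each of the `n_perm` (default
5000) permutations draws the same number of positions uniformly without
replacement from the LCC and attaches the observed phase multiset to them
in random order — positions are permuted rather than phases, though the two
are marginally equivalent under uniform draws. Each permutation preserves
the number of cyclers and the phase multiset by construction. The
empirical p per distance class is the one-sided add-one estimator
$(1 + \#\{\text{null} \le \text{obs}\})/(1 + \#\text{valid permutations})$,
bounded below by $1/(n_{\mathrm{perm}}+1)$ and never 0; classes that come
up empty in a permutation are recorded as missing for that permutation, not
as zero, and drop out of that class's denominator. The default alternative
is one-sided ("closer pairs more similar than null") because that is the
scientific claim; `two.sided` is available. The full null-median matrix is
stored in the result so every reported p can be re-derived from it.

# The synthetic-data generator

The generator exists so that calibration and power are measurable, and its
defaults are the study conditions the package is designed around:

* **Sampling**: every 2 h over a stable two-day window (ZT 0–46, 24
  timepoints), one replicate per timepoint (replicate counts are
  configurable; published designs of this type rarely state them
  explicitly), two experiments.
* **Truth**: a configurable minority of genes cycle (network studies here
  use 20%, about 100 cyclers on a 500-node graph; genome-scale
  simulations use the ~5% detection rates typical of a single tissue).
  Baseline TPM is lognormal (meanlog = log 30, sdlog = 0.8) so most genes
  clear a median-TPM > 5 filter, and cycling amplitude defaults to half
  the mesor — a moderately strong oscillator.
* **Noise**: multiplicative lognormal with CV 0.2, applied to the cosinor
  mean. TPM is analysed directly, so noise is placed on TPM; a
  count-level negative-binomial layer is deliberately out of scope.
* **Replication error**: each gene's phase is jittered per experiment by
  N(0, 0.5 h), so the two experiments agree imperfectly, as real replicated
  designs do.
* **Phase organization** is planted by iterated local circular averaging:
  phases start uniform, then each cycling node's unit phasor is pulled
  toward the mean phasor of its cycling neighbours with strength
  `coupling`, for `n_smooth` rounds, and renormalised. This is not a
  generative probabilistic model (no explicit Markov random field); it is a
  simple, controllable mechanism that provably yields the
  distance-decaying phase similarity the organization test targets, with
  `coupling = 0` recovering exactly independent uniform phases — the
  calibration case.

All randomness flows from one master seed through named substreams
(`network`, `planting`, `noise_*`, `permutation`), so each stage is
independently reproducible and the fixture writer emits byte-identical
files for identical seeds.

What the generator does *not* emulate — read-level noise, transcript
quantification error, unbalanced library sizes, condition-dependent
expression changes in non-cycling genes, correlated noise across genes —
bounds what green tests mean: they demonstrate the statistics are correct
and calibrated under the stated model, not that any particular biological
dataset satisfies that model.

# Calibration and power, as run by the test suite

The acceptance-style tests exercise the whole chain at fixed problem sizes
chosen to make each property measurable with stable Monte Carlo error
while keeping the default suite fast:

* Null calibration of the dual criterion: 200 two-experiment datasets of
  2000 flat noisy genes; the mean call count must lie within 3 binomial
  SEs of the closed-form expectation (5.0 at this size).
* Phase recovery: noiseless planted cyclers are recovered with 100%
  sensitivity and < 0.1 h phase error; at noise CV 0.2 the median consensus
  phase error stays under 1 h.
* Permutation calibration: with `coupling = 0`, 100 datasets (500-node
  Erdős–Rényi graph with mean degree 8, 100 cyclers, 500 permutations)
  give neighbour-class empirical p-values consistent with uniform (KS).
  The Erdős–Rényi model with mean degree 8 is the package's reference
  graph for these studies: connected at this density, small diameter, and
  free of degree hubs that would complicate interpretation.
* Power: with `coupling = 0.9`, `n_smooth = 20` and noise CV 0.05, the
  neighbour class reaches p < 0.05 and the trend slope is positive in well
  over 90% of seeds.
* Oracle equivalence: circular distances against a brute-force wrap
  search on 10^6 pairs; BFS distances against an independently written
  all-pairs BFS; circular correlation ±1 on identity/reflection.

# Numerical and design notes

* Phases are reported in $[0, 24)$ with values within $10^{-9}$ h of 24
  snapped to 0, avoiding `23.999999999` artefacts from `atan2` round-off.
* The expression filter retains a gene when its median TPM exceeds the
  threshold (strictly) in at least one condition within *every* experiment
  — the reading under which "consistently" binds experiments. Medians are
  per experiment, over all of that experiment-condition's samples; whether
  to pool experiments first is genuinely ambiguous in this kind of design,
  and per-experiment is the stricter, replication-consistent choice.
* The cycling call excludes genes absent from either experiment's fit
  table (logged), and flat genes (phase `NA`) can never be called.
* `localization_test` on `subset = all nodes` compares a distribution with
  itself and correctly hovers near p ≈ 0.5 one-sided.
* Known limitations: the harmonic F-test assumes roughly Gaussian
  residuals — under strong multiplicative noise its null rate at p < 0.1 is
  only approximately 10% (the replication criterion absorbs most of the
  slack, and the calibration test quantifies it); the KS tests on discrete
  degrees use the asymptotic distribution in the presence of ties; and the
  permutation null holds the network fixed, so it conditions on the
  observed graph rather than modelling graph uncertainty.
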