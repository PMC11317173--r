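---
title: "Methods: EM-based clonal decomposition of non-tumor samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EM-based clonal decomposition of non-tumor samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declone)
```

## The problem

Bulk sequencing of normal (non-tumor) tissue mixes several somatic clones
whose variant allele frequencies (VAFs) are low, similar to one another,
and contaminated by sequencing artifacts. `declone` decomposes per-variant
read counts from one or more samples of the same specimen into individual
subclones, ancestral superclones and a false-variant (FV) cluster. Two
facts about normal diploid tissue carry most of the statistical weight:
there are no copy-number alterations, and somatic variants are
heterozygous. Together they imply that the VAF centroids of the mutually
exclusive ("individual") clones must sum to 0.5 in every sample, and that
an undifferentiated ancestral clone's centroid must equal the sum of its
descendants' centroids. These constraints are what allows the clone number
to be pinned down even when clusters overlap heavily.

## Model and algorithm

**Inputs.** An m x n table of total and alternate read counts, an optional
per-variant Phred base quality (converted to a sequencing-error probability
`p = 10^(-BQ/10)`; 0.01 by default), and per-sample sex. Male sex-chromosome
depths are doubled once, guarded by a calibration flag, so the heterozygous
diploid VAF scale applies everywhere. VAF is `alt/total`, defined as 0 at
zero depth; zero-depth entries contribute a factor of one to all
likelihoods rather than an undefined term.

**Mixture.** k true clusters with per-sample centroids plus one FV cluster
fixed at the origin. The E step selects the likelihood by case: with
alternate reads present, a non-zero-centroid cluster is scored by a
beta-binomial whose pseudo-counts are moment-matched to the centroid
(`alpha = mu * n * c`, `beta = (1-mu) * n * c`; the multiplication constant
`c` is user-tunable for over- or under-dispersed data), and a zero-centroid
cluster by a binomial error model `B(n, p_SE)`. With zero alternate reads
the same two likelihoods act as the false-negative and true-negative cases,
and the zero-centroid clusters share a prior mass of 0.99. With alternate
reads present each zero-centroid cluster has prior 0.01 and the remainder is
split evenly across true clusters. Per-sample posteriors multiply across
samples (independent sampling of the same clonal structure) and are
renormalized. Hard clustering takes the one-hot argmax (ties toward the
lower cluster index); fuzzy clustering takes the posterior itself. The M
step is the membership-weighted mean VAF per cluster; the FV centroid never
moves. True centroids are clamped to `[1e-6, 1 - 1e-6]` because the
pseudo-counts degenerate at the boundary; a cluster whose total membership
falls below `1e-12` is dropped and the candidate clone number shrinks.

**Stopping.** At least 11 iterations, then any of: relative objective
change below 1%, all centroid moves below 0.01, or an unchanged membership
matrix; a hard cap of 20 iterations applies regardless. The objective is
the marginal log-posterior summed over variants. This modified EM (priors
switch by case, membership may be hard) has no monotonicity guarantee; the
test suite checks that dips in the objective trace are marginal rather than
forbidding them.

**Structure tests.** On every converged solution the candidate individual
set is chosen among all non-empty subsets of true clusters by a multisample
t-test of the null "centroid sum = 0.5 per sample", using cluster-member
VAFs as observations (fuzzy memberships enter as weights with effective
counts). Degrees of freedom are pooled (`sum(n) - k'`) unless a
two-sample F test between the most and least dispersed member cluster
rejects homogeneity at 0.05, in which case Welch-Satterthwaite is used.
The passing subset with the highest combined (minimum-across-samples)
p-value wins; every remaining cluster must then pass the analogous sum-rule
test against some subset of at least two individual clones, which defines
the superclone edges. Any failure discards the restart. Two
implementation choices deserve note:

* *Per-sample level.* The test is stated at significance 0.01 for the
  multisample null "for all samples". We split the level across samples
  (Bonferroni, `alpha/m` per sample): rejecting whenever any single sample
  rejects at `alpha` would inflate the combined level to roughly
  `m * alpha` and measurably rejects the true clone number in three-sample
  runs.
* *When to test.* Structure is checked on converged solutions rather than
  inside every EM iteration. An accepted model is identical under both
  schedules (it must pass at convergence either way); checking early
  iterations would only discard runs that pass through transient
  configurations, at roughly tenfold cost.
* *Sum rule on hardened memberships.* In fuzzy mode the subclone rule uses
  the posterior-weighted member statistics, but the sum rule is evaluated
  on the hardened (argmax) membership. Posterior sharing between
  overlapping fuzzy clusters inflates the weighted variances so much that
  the superclone test loses the power to reject spurious ancestral
  explanations, which otherwise admit split-clone solutions two clusters
  above the true clone number. Hardening by argmax is also how fuzzy
  memberships are converted whenever a binary assignment is required.

**Restarts and feasibility.** Initial centroids come from one seeded
K-means partition of the VAF vectors into T = 10 clusters (multi-start
`stats::kmeans`; reproducibility is the point, the specific seeding variant
is not), from which k are drawn uniformly per restart, 10 restarts per
candidate k. Identical draws are memoized - the EM is deterministic given
its start. A candidate k is *feasible* when some restart yields a
structure-consistent model. Hard clustering is tried first; if no hard
restart passes, fuzzy restarts are tried at that k. This matters on
agglomerated data: hard assignment truncation-biases slice means (their sum
falls visibly below 0.5 at the true k), while the fuzzy fit, whose
beta-binomial components have fixed width, passes at the true k and fails
at neighboring k. Two parsimony windows shape the search: the fuzzy route
is only granted to candidates no more than two above the smallest feasible
k found so far (a larger candidate should not become feasible through the
statistically weaker fuzzy tests when a smaller one already explains the
data), and before the smallest feasible k is accepted, the one or two
candidates directly below it receive a second wave of provisional clone
sets, so an overestimate cannot win merely because the first draws at a
smaller k missed its convergence basin.

**Choosing k and the output mode.** Among feasible candidates the clone
number maximizes the starred (non-logarithmic) gap statistic: mean
within-cluster dispersion of B = 10 reference datasets drawn uniformly over
the observed per-dimension VAF range minus the observed dispersion, both
computed by the same K-means procedure at the same k, with FV-assigned
variants excluded and ties resolved toward smaller k. The absolute-scale
gap was chosen over the log-scale variant after the latter systematically
preferred split-plus-spurious-ancestor solutions at k+1 on dispersed
simulations. If no candidate is feasible at all, the pipeline reports the
model whose full set of true clusters comes closest to the 0.5 sum rule
(highest full-set p across hard and fuzzy runs) and flags the fit as
`forced`; the full-set statistic is comparable across k, unlike the
best-subset p, which grows mechanically with the number of available
subsets. Finally, the fuzzy solution replaces the hard one when the hard
posterior's maximum pairwise Jaccard overlap strictly exceeds 0.2, and
variants whose membership argmax is the FV cluster are labeled false
variants.

## The simulator

`generate_sim_dataset()` emulates the benchmark conditions: 500 variants at
mean depth `N(125, 8)` (SD interpreted as a standard deviation; a variance
of 8 would imply an implausibly tight depth distribution), rounded and
floored at one read; clone proportions drawn per sample from a Dirichlet
with binomially sampled shapes - `B(10y, 0.5)` per clone y in the
dispersed *decoy* regime, `B(10k, 0.5)` for all clones in the agglomerated
*lump* regime, shapes floored at 1 to avoid a degenerate Dirichlet; true
variants allocated to clones by a uniform multinomial; heterozygous alt
counts `Binomial(total, rho/2)` so the expected VAF is half the clone
proportion (the alternative reading `B(total * rho/2, 0.5)` contradicts
that stated property and was rejected); and false variants with VAFs drawn
from the normalized reverse-sigmoid density proportional to
`1/(1 + exp(100 f - 5))`, independently per sample, realized as binomial
alt counts. The printed form of that density (with the sigmoid rising in
f) integrates to a mean of 0.52 and cannot be the intended model; the
reverse-sigmoid form used here has mean 0.028 and median 0.026 by
quadrature on a 1e-4 grid, matching the reference values 0.029/0.027 to
the reported precision. Base quality is 20 for every simulated variant.

What the simulator does *not* emulate: cross-sample false-negative
structure from per-sample variant calling, clone-specific dropout,
mutational signatures, or correlated sequencing artifacts. Passing the
simulation benchmark therefore demonstrates correct recovery under the
generative model above, not performance on real call sets.

## Numerical and design choices

* Beta-binomial likelihoods are computed in log space via `lgamma`
  identities (no factorial overflow at depth 250+); the compiled kernel
  caches the depth-dependent `lgamma` terms per distinct depth.
* The compiled EM kernel and a plain-R reference implementation of every
  step are both part of the package and asserted to agree; the pipeline
  uses the kernel.
* Argmax ties break toward the lower cluster index everywhere.
* Standard errors in the structure tests are floored at `1e-6` for
  degenerate (all-identical) clusters.
* The membership score is computed as an exact maximum-weight injection by
  bitmask dynamic programming and is cross-checked against brute-force
  enumeration in the tests.
* Problem sizes in the test suite follow the benchmark conditions
  (n = 500, depth 125); replicate counts per configuration are 10 for the
  clone-number benchmarks and 5 per cell for the false-variant grid.

## Known limitations

* Single-sample decomposition of agglomerated or very-low-VAF clones is
  intrinsically underdetermined; the 0.5-sum constraint recovers the clone
  number, but memberships between overlapping clones remain fuzzy.
* Variants of a real clone that show zero alternate reads are absorbed by
  the FV cluster (by design); for clones near VAF 0.01 this truncation
  biases the surviving cluster mean upward and is the main residual source
  of clone-number misses.
* The phylogeny is a depth-one forest (superclone to individual subclones);
  multi-level ancestry is out of scope.
* Copy-number-aware modelling is deliberately excluded; the method's
  premise is copy-number neutrality.
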