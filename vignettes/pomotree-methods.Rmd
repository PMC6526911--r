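---
title: "Boundary mutation models for species tree inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary mutation models for species tree inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pomotree)
```

## The model

pomotree infers species trees from allele-count alignments: for each of
several populations and each genomic site, the number of sampled copies
of each nucleotide. The evolving character is the state of a virtual
population of `N` haploid individuals, which is either monomorphic,
`{a}`, or polymorphic for two alleles, `{i a | (N-i) b}` with
`i = 1..N-1`. `N` is a discretization parameter — the number of bins
allele frequencies can fall into — not an effective population size:
scaling population size down while scaling mutation rates up leaves the
neutral dynamics unchanged. For nucleotides and `N = 10` the chain has
`4 + 6*9 = 58` states.

The generator decomposes as `Q = Q_M + Q_D`:

* `Q_M` moves monomorphic states to adjacent polymorphic ones,
  `{a} -> {(N-1)a|1b}`, at mutation rate `q_ab` taken from a reversible
  nucleotide model (`q_ab = mu * rho_ab * pi_b`; JC, HKY, GTR, or any
  symmetric exchangeability matrix). Mutation is disallowed while the
  population is polymorphic — the *boundary mutation* assumption. It is
  a good approximation while drift resolves variation quickly relative
  to the mutation rate, i.e. while heterozygosity is below roughly 0.1;
  `calibrate_heterozygosity()` warns above that value.
* `Q_D` is the continuous-time Moran drift: `{i a|(N-i) b}` moves to
  `i ± 1` at rate `i (N-i) / N`, including absorption into the
  monomorphic boundaries.

Because every supported mutation model is reversible, the stationary law
has a closed form (monomorphic mass proportional to `pi_a`; polymorphic
mass proportional to `mu * rho_ab * pi_a * pi_b * N / (i (N-i))`), which
the package uses throughout and cross-checks against numeric null
eigenvectors in its tests.

### Heterozygosity calibration

The overall mutation magnitude `mu` is not a user-facing unit; instead
the model is pinned to a target heterozygosity `theta`, operationalized
as the **total stationary polymorphic probability mass**. This choice is
monotone in `mu` (so a 1-D root solve inverts it exactly), matches the
small-`theta` boundary-mutation regime, and is self-consistent between
the simulator and the likelihood engine. It is worth stating the
alternative: sample-based definitions (Watterson's estimator on `M`
sampled alleles, or expected pairwise diversity) would assign the same
nominal `theta` a polymorphic mass roughly 3 times larger at `N = 10`.
All quantitative statements in this package use the stationary-mass
definition.

### Branch-length units

`Q` is normalized so one unit of branch length is one expected event —
mutation or frequency shift — per site at stationarity; the
pre-normalization rate is exposed as `$scale`. At stationarity the total
event flux equals `N` times the mutation flux out of monomorphic states
(each mutation triggers on average `N - 1` subsequent drift events), and
the substitution rate is the mutation flux times the Moran fixation
probability `1/N`. One expected substitution per site therefore equals
exactly `N^2` expected events, independent of the mutation parameters
(`events_per_substitution()`). Species-tree heights quoted in
substitutions per site — the customary unit — are converted by this
factor when the simulator samples Yule trees (`height_units`
argument). This conversion matters: at `N = 10` a tree of height 0.01
substitutions is 1.0 event units tall, and treating the two scales as
interchangeable shortens trees 100-fold and destroys essentially all
signal about rate heterogeneity.

### Gamma mutation-rate heterogeneity

A single global rescaling of `Q`, as in classical Gamma-rates models,
would wrongly accelerate drift alongside mutation. Instead heterogeneity
enters as a mixture: `K` equal-probability categories with rate
modifiers `r_k` — the slice means of a mean-one Gamma(`alpha`)
distribution, computed via incomplete-gamma integrals and renormalized
to mean one — define `Q_k = r_k Q_M + Q_D`, and the site likelihood is
the unweighted mean of the per-category pruning likelihoods. Each `Q_k`
is reversible with its own stationary law and needs its own
eigendecomposition; the engine caches all `K` decompositions per
parameter vector. All categories share one normalization constant, taken
from the weighted-average generator (equal to the homogeneous `Q`
because the modifiers average to one), so a branch length means the same
thing in every category; per-category normalization would distort the
semantics of the modifiers. Shapes below 0.01 are rejected as
numerically degenerate and shapes at or above 1e6 are treated as
homogeneous.

### Leaf likelihoods for `M != N` samples

An observation of `M` sampled alleles must be mapped onto states that
track `N` frequency bins. Three strategies are provided:

* **weighted binomial** (default): state `{i a|(N-i) b}` receives the
  probability that `M` draws *with replacement* from allele frequency
  `i/N` produce the observed counts. Monomorphic observations give
  polymorphic states nonzero weight, so heterozygosity is slightly
  overestimated; polymorphic observations zero out monomorphic states.
* **weighted hypergeometric**: draws *without replacement*; exact
  (an indicator) when `M = N`, undefined when `M > N` (error).
* **sampled**: binomially resample `N` alleles from the observed
  frequencies and commit to the single resulting state; one seeded draw
  per site in site order, so runs are reproducible.

Monomorphic states are treated as the `i = N` / `i = 0` boundaries of
every compatible allele pair, counted once. Sites with three or more
segregating alleles cannot be represented and are rejected at
likelihood initialization (file parsing succeeds; the error is raised
by the analysis that consumes the site).

## Inference

The likelihood is the standard pruning recursion over the PoMo state
space, with per-node column rescaling against underflow, stationary
closure at the root (root placement is immaterial under reversibility —
asserted by test, not assumed), and site patterns compressed on the full
tuple of per-population counts. Optimization is coordinate-wise: Brent
line searches on log scales for `theta` (bounds 1e-6..0.25), `kappa`
(0.2..100), GTR exchangeabilities (1e-3..1e3, GT pinned to 1), `alpha`
(0.01..1e6), followed by per-edge branch length optimization
(1e-8..10). Branch lengths use a two-pass scheme — postorder partials,
then a preorder traversal maintaining the "rest of tree" vector per edge
— so each one-dimensional branch optimization costs two small matrix
products up front and trivial Brent iterations thereafter. Sweeps repeat
until the relative log-likelihood improvement falls below `rel_tol`
(default 1e-6; recovery experiments in the tests tighten this).
Stationary frequencies default to pooled empirical counts frequencies
(`pi_mode = "empirical"`, contributing `|A|-1` free parameters to
information criteria, the convention of mainstream ML phylogenetics
software); ML estimation of `pi` is available, as is freezing any
parameter subset — frozen values are returned bit-for-bit.

Topology search is deliberately small-scale: exhaustive enumeration
(guaranteed ML topology) up to 8 populations, NNI hill-climbing beyond;
large-scale heuristics are out of scope. The nonparametric bootstrap
resamples site patterns by a weighted multinomial — identical in
distribution to resampling columns, much faster — and reports per-split
support; support is only informative when the topology is re-searched
per replicate (`search = TRUE`), otherwise refitting branch lengths on a
fixed topology trivially yields 100%. Model ranking refits each
candidate and scores `AIC = 2k - 2 lnL`, `BIC = k ln(n_sites) - 2 lnL`
with a stable sort.

## The simulator

`simulate_counts()` generates data under exactly the model the engine
assumes — the point is validation by parameter recovery. Per site: a
category is drawn uniformly; the root state is drawn from that
category's stationary law; states evolve down the tree by sampling rows
of `exp(Q_k t)` (exact at the embedded-chain level — not event-by-event;
a Gillespie mode, `simulate_branch_gillespie()`, cross-validates the
transition kernels at small scale); each leaf is observed as `M`
binomial draws from the leaf state's allele frequency, matching the
weighted-binomial reading of the data. Fixed seeds give bit-identical
counts files.

Yule trees are sampled forward from the root split (two lineages),
truncated at exactly height `h` with contemporaneous tips, with
speciation rate `lambda = (sum_{i=1..n} 1/i - 1)/h` — the inverse of the
expected root age of an `n`-tip Yule tree. Because the expectation is
inverted, the *realized* leaf count at fixed height is random with mean
`2 exp(lambda h)` (about 16 for a nominal `n = 12`), not `n`; the tests
assert the analytic expectation. Conditioning on height rather than leaf
count mirrors how the recovery experiments are described.

### What the simulator does and does not emulate

Simulated data share the engine's assumptions exactly: free
recombination (independent sites), a single shared `N` across
populations, no selection, no migration, reversible stationary mutation,
and sampling that matches weighted-binomial initialization. Passing
recovery tests therefore demonstrates correctness and statistical
efficiency of the implementation, not robustness to the many ways real
resequencing data violate these assumptions (linkage, population
structure, sequencing error, reference bias). The multispecies
coalescent is *not* simulated; the boundary mutation model's own account
of incomplete lineage sorting — ancestral polymorphism carried across
splits — is what is being exercised.

## Numerical choices

* Matrix exponentials via symmetrized eigendecomposition
  (`D Q D^-1` symmetric for `D = diag(sqrt(pi))`); negative entries from
  rounding are clamped at 0 and rows renormalized; an independent
  scaling-and-squaring implementation serves as test oracle.
* Stationary laws: closed form for reversible models; numeric fallback
  via eigendecomposition of `t(Q)` with an augmented-linear-system
  rescue, clamped at zero and renormalized.
* Underflow: per-node column scaling with accumulated per-pattern log
  factors; mixture combination by log-sum-exp.
* Calibration root solve: `uniroot` on log `mu`, bracket 1e-12..1e8,
  tolerance 1e-14.
* Degenerate inputs: `t = 0` returns the identity; zero-length branches,
  missing observations (all-ones leaf vectors) and `M = 0` sites
  (treated as missing with a warning) are all legal.

## Problem sizes used by the test suite

The published recovery experiments use one million sites and ten
replicates; this package's own experiments are scaled to what a single
processor exercises comfortably: the Gamma-shape/kappa/branch-length
recovery harness runs 3 replicates per shape value (0.3, 1.0, 5.0) at
100,000 sites on 12-taxon Yule trees (draws conditioned on the leaf
count) of height 0.01 substitutions per site, with `N = 10`, `theta = 0.0025`, `kappa = 6.25`, `K = 4`, ten
sampled alleles per population — the published parameter set at reduced
length. At this length the sampling error of the Gamma-shape estimate is
substantial (the likelihood-profile curvature puts its standard error
near 15-20%, shrinking like the square root of the site count), whereas
the ts/tv ratio is recovered to a fraction of a percent; the
branch-score accuracy criterion inherits the same square-root scaling.
The high-heterozygosity robustness check uses 12-taxon trees of height
`0.75 * theta` substitutions — the analog of the published
3-Ne-generations setting under `theta = 4 N_e mu` — at
`theta ∈ {0.01, 0.1}`, with a paired design (the smaller data set is a
prefix of the larger one) so that "more data gives better trees" is
assessed without between-replicate tree noise.

## Known limitations

* At most two alleles per site; triallelic observations are rejected
  rather than collapsed.
* Nonreversible (Lie-Markov) mutation models, selection, amino-acid
  alphabets, invariant-sites categories and free-rate category models
  are out of scope.
* `N` is global; per-population discretization is not supported.
* The optimizer is a coordinate scheme with bounded line searches; it is
  robust for the intended parameter counts (tens of branches plus a few
  model parameters) but is not a general large-scale tree search.
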