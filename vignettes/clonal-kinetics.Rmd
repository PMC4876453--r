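---
title: "Clonal growth kinetics from serial tumour sequencing"
author: "clonekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal growth kinetics from serial tumour sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonekin)
```

# The problem

Targeted therapy in chronic lymphocytic leukaemia (CLL) exerts strong
selective pressure on the leukaemic population. Relapse is typically driven
by subclones that were already present — at frequencies far below the
sequencing detection limit — when therapy started. Because CLL circulates,
serial blood draws give both deep sequencing of somatic mutations and an
absolute scale: the absolute lymphocyte count (ALC, cells/µl). Combining
the two yields absolute per-clone cell counts over time, from which
per-clone growth and decline rates and the pre-treatment size of the
resistant clone can be estimated.

`clonekin` implements that analysis as a tested pipeline: cancer cell
fraction (CCF) posteriors from read counts, mutation clustering into
subclones across serial samples, clone-tree inference under lineage
constraints, absolute clone trajectories, exponential rate fits with
posterior-propagated confidence intervals, and back-extrapolation to the
day therapy started. It also implements the statistics of two orthogonal
rare-cell assays (droplet digital counting and allele-specific single-cell
genotyping) used to confirm such back-extrapolations, and a synthetic
cohort generator so every stage is testable against known truth.

# Model

## From read counts to CCF

For a mutation with alt/ref read counts in a sample of purity $p$, local
total copy number $q$ and mutant multiplicity $m$, the expected variant
allele fraction at cancer cell fraction $c$ is

$$ f(c) = \frac{p\, m\, c}{p\, q + 2(1 - p)} . $$

The likelihood of the observed counts is binomial in $f(c)$; with a uniform
prior over a discrete grid on $[0, 1]$ this gives a posterior mass function
per mutation per sample (`afToCCFPosterior()`, `computeCCF()`). The
multiplicity defaults to 1; `multiplicity = "auto"` uses the nearest
integer implied by the observed allele fraction under the clonal
assumption, clamped to $1..q$. (Maximising the likelihood over $m$ directly
is degenerate — $m = q$ paired with a proportionally smaller CCF always
fits at least as well — so the nearest-integer convention, standard in
subclonal reconstruction, is used instead.) Mutations in regions with
germline copy-number variants should be excluded upstream; purity and copy
number are inputs, not estimated here.

## Clustering

Mutations are clustered by their CCF vectors across all serial samples with
a finite mixture fitted by EM (`clusterCCF()`): each component is one CCF
centre per sample and a mutation's component likelihood is the product over
samples of its binomial likelihood at the centre. The number of components
is chosen by BIC over $k = 1..k_{max}$. Initialisation is
k-means++-style seeding on the per-mutation point CCFs with 10 restarts;
ties are broken toward lower $k$, then the earlier restart, making the fit
deterministic given the seed. Cluster-level posteriors are grid-wise
products of member posteriors.

A numerical point that matters: EM centres are *continuous* (the weighted
binomial maximum-likelihood solution), not grid points. With several
mutations per cluster at 1000× depth the cluster likelihood is sharper than
any practical grid, and grid-restricted centres caused systematic BIC
oversplitting at low CCF where the quantisation error exceeds the binomial
noise. Posterior *reporting* remains on the grid.

## Clone tree

Subclones are related by a rooted tree over clusters (germline root, clonal
"trunk" cluster with CCF $\approx 1$ in every sample). Two per-sample
constraints define admissibility, both up to a tolerance $\varepsilon$:

* crossing rule — a child's inclusive CCF cannot exceed its parent's;
* pigeonhole rule — the children of a node cannot sum to more than the
  node's CCF.

`enumerateValidTrees()` enumerates all rooted trees over the clusters
(exhaustive, bounded at 8 clusters) and keeps the admissible ones;
`scoreAndSelectTree()` scores each candidate by the joint posterior
probability that CCFs drawn from the cluster posteriors satisfy its
constraints exactly (common random draws across candidates), returning the
maximal-score tree with ties broken toward shallower trees, then the
lexicographically smaller parent map. When no tree is admissible the
least-violating tree is returned with a flag rather than failing, so noisy
data still produce a diagnosable result. Note that when one subclone's CCF
stays below a sibling's at every sampled day, chain and sibling topologies
are genuinely indistinguishable from CCFs alone; crossing dynamics (one
clone declining while another grows) are what identify the topology.

Exclusive fractions — the share of cancer cells in a clone but none of its
descendants — are inclusive CCF minus the children's inclusive CCFs,
floored at zero with the clipped mass reported.

## Absolute counts and kinetics

The total circulating CLL population is taken as
$\mathrm{ALC} \times V \times 10^6$ cells with $V = 5$ l of peripheral
blood by default; the ALC is treated as entirely leukaemic (an optional
tumour-fraction multiplier is provided for partial remissions). Clone
counts are fraction × total, using exclusive fractions by default so clone
counts sum to the total (`--ccf-mode inclusive` is available because the
field's phrase "multiplying the CCF" is ambiguous). A clone is *detected*
at a day when its point fraction is at least 0.01, matching the 1%-of-total
convention used for upper bounds on undetected clones
(`undetectedUpperBound()`).

Each clone grows or declines exponentially at a constant rate $g$:
$N(t) = N(0)\,e^{g t}$, with $t$ in days and day 0 the start of therapy.
With exactly two detected observations,
$g = \ln(N_2/N_1)/(t_2 - t_1)$ and the uncertainty is the s.d. of $g$ over
Monte-Carlo resamples of the CCF posteriors; with more, $g$ is the OLS
slope of $\ln N$ on $t$ and the regression s.e. is reported. 95% intervals
for $g$ and for the back-extrapolated day-0 size $N_0 = e^{\hat a}$ are
posterior-percentile based: cluster CCFs are resampled jointly from their
posteriors, exclusive fractions and counts recomputed, and the fit
repeated per draw (`cloneGrowthFits()`; the detected-day set is frozen at
the point estimates across draws, and non-positive resampled counts are
floored at 1 cell). When the earliest usable point is an upper bound the
fitted rate is flagged as a *lower* bound (the ">x% per day" convention).
Sibling clones can be constrained to a common rate with clone-specific
intercepts (`fitSharedRate()`), and a clone with too few direct
measurements can be fitted from the unexplained ALC residual
(`fitRateFromALC()`). `predictALC()` reports the log-domain RMSE of the
summed model against the observed ALC series.

## Assay statistics

For droplet digital quantification: occupancy under Poisson loading is
$1 - e^{-\lambda}$ (assays are loaded below 30% occupancy, i.e.
$\lambda < -\ln 0.7 \approx 0.357$, to keep multiple occupancy rare);
mutant-cell frequencies carry exact Clopper–Pearson intervals, appropriate
at $10^{-4}$–$10^{-6}$ where normal approximations fail; unknowns are
quantified against a log–log least-squares standard curve with
out-of-range estimates flagged. For single-cell genotyping: background
mutant-allele signal is regressed on the normal-allele signal over
known-negative cells; the background-corrected fractional mutant allele
$f = m'/(n + m')$ is called normal below 0.15, mutant above 0.3, unclear in
the closed interval $[0.15, 0.3]$ (boundary values are deliberately
conservative), and excluded when neither allele is detected (0/0).
Technical replicates are averaged before calling.

# The synthetic generator

`SimConfig()`/`simulateClonalDynamics()` define a clone tree with exclusive
per-clone sizes at day 0 and constant exponential rates; exclusive counts
are the primary bookkeeping and inclusive CCFs are derived, which prevents
double counting by construction. The defaults emulate the study conditions
this package targets: a dominant clone declining at 0.2%/day and rare
resistant subclones (3 × 10^6 and 2.7 × 10^4 cells at day 0) growing at
1.5 and 1.9%/day, sampled at days 0/365/730/985 at depth 1000× and purity
0.9, with 5 private mutations per clone and 5 l blood volume.
`simulateSequencing()` draws per-mutation depths Poisson around the mean
and alt counts binomially at the model allele fraction; a per-base error
rate is available (`errorRate`, default 0 so oracle tests are exact; 10^-3
is a realistic value). `simulateAssayData()` draws droplet positives at the
clone's true prevalence and single-cell signals with a configurable linear
background.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: mutation acquisition over time (clone
genotypes are fixed at day 0), lymph-node/blood redistribution (a known
effect of BTK inhibition), overdispersed sequencing noise, purity
estimation error, and copy-number mis-segmentation. Rates are exactly
constant in the generator; on real data constancy is an assumption checked
only indirectly through the ALC fit.

# Numerical choices

* CCF grid: step 0.001 in the pipeline (`computeCCF()`), step 0.01 for
  single-mutation posteriors (`afToCCFPosterior()`). Cluster posteriors are
  products over members, with s.d. ≈ 0.007 under the default study design,
  so the pipeline grid must be finer than that; 0.001 keeps quantisation
  an order of magnitude below the noise at negligible cost. Fractions below
  ~grid resolution are not representable — detected points should sit well
  above it (the 0.01 detection threshold guarantees this at the default
  step).
* Likelihood clamping: model allele fractions are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ so grid endpoints keep finite log-likelihood.
* Posterior mode ties break toward the larger CCF; EM restarts tie-break
  toward the earlier restart; tree-score ties toward shallower trees then
  lexicographic parent maps. All randomness flows from explicit seeds.
* Monte-Carlo defaults: 1000 draws for tree scoring and CI propagation
  (tests use 300–400 for speed; CIs change negligibly).
* $\varepsilon = 0.10$ on point CCFs for tree admissibility, sized to
  absorb binomial noise at moderate depth; posterior-aware scoring uses
  exact constraints on the draws.
* Degenerate inputs are rejected with explicit messages (cycles in parent
  maps, non-positive sizes or depths, purity outside (0,1], zero counts
  among detected points), and the pipeline downgrades gracefully
  (single-sample patients skip kinetics; unfittable clones are reported
  with `insufficient_data`).

# Problem sizes in the test-suite experiments

The suite's simulation experiments use the study-scale design above: 200
replicates for rate recovery and back-extrapolation (median absolute rate
error ≤ 0.002/day, ≥ 90% CI coverage, N0 within a factor of 3 for clones
of ≥ 100 cells), 100 random ≤ 5-cluster instances for the tree oracle, 50
replicates for clustering accuracy, and 500 replicates for frequency-CI
coverage; exact enumeration replaces sampling wherever a closed-form
oracle exists (binomial mode probabilities, Clopper–Pearson coverage, the
0.15/0.3 genotype partition).

# Known limitations

* Purity and copy number are trusted inputs; no joint purity/ploidy
  estimation is attempted.
* Clustering assumes binomial noise; real targeted panels are often
  overdispersed, which would favour more clusters than BIC should allow.
* Chain-versus-sibling topologies are unidentifiable without crossing
  dynamics, and the constraint-mass score then prefers chains (fewer
  binding constraints).
* Back-extrapolation assumes the fitted rate held from day 0, exactly the
  assumption the assays exist to check.
* The ALC is treated as pure CLL; in deep remission this overstates the
  leukaemic total unless the tumour-fraction multiplier is set.
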