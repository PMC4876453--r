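# clonekin

Clonal growth kinetics from serial tumour sequencing.

## What it is for

When a chronic lymphocytic leukaemia (CLL) relapses on a targeted agent,
the clone driving relapse was usually present — at one in thousands to one
in millions of cells — before therapy began. Because CLL circulates, each
blood draw provides two things at once: deep sequencing of somatic
mutations and an absolute scale, the absolute lymphocyte count (ALC,
cells/µl). `clonekin` turns a series of such draws into per-clone
population dynamics:

1. **CCF inference** — per-mutation cancer cell fraction posteriors from
   alt/ref read counts, given sample purity and local copy number. The
   expected allele fraction at CCF *c* is
   `af(c) = p·m·c / (p·q + 2(1−p))` with purity *p*, total copy number
   *q*, mutant multiplicity *m*; the read-count likelihood is binomial.
2. **Clustering** — an EM finite mixture over multi-sample CCF vectors,
   components selected by BIC, groups mutations into subclones.
3. **Clone phylogeny** — exhaustive enumeration of rooted clone trees
   obeying the lineage ("pigeonhole") constraints in every sample, scored
   by Monte-Carlo posterior constraint mass.
4. **Growth kinetics** — clone fractions × (ALC × 5 l × 10⁶) give absolute
   counts; each clone is fitted as a constant-rate exponential
   `N(t) = N₀·e^{g·t}` (two-point closed form or log-domain OLS), with 95%
   intervals from Monte-Carlo resampling of the CCF posteriors, 1%-of-total
   upper bounds for undetected clones, and back-extrapolated day-0 sizes
   `N₀` reported as "1 in N of total CLL cells".
5. **Assay statistics** — droplet digital rare-cell quantification
   (Poisson loading, standard curves, exact Clopper–Pearson intervals) and
   allele-specific single-cell genotype calling (background regression,
   0.15/0.3 thresholds) for orthogonal confirmation of rare-clone sizes.
6. **Synthetic cohorts** — a generator with known ground truth (clone
   trees, exponential trajectories, ALC series, read counts, assay
   signals) so every stage is testable without patient data.

The methods vignette (`vignettes/clonal-kinetics.Rmd`) documents the model,
assumptions, numerical choices and limitations.

## Worked example

Simulate a patient with a dominant clone declining at 0.2%/day and a
resistant subclone of 10⁶ cells growing at 1.9%/day, sampled on days
0/365/730/985 at 1000× depth, then run the full pipeline on the written
tables:

```r
library(clonekin)
cfg <- SimConfig(nClones = 2L, parent = c(0L, 1L),
                 initialSizes = c(1e11, 1e6), ratesPerDay = c(-0.002, 0.019),
                 sampleDays = c(0, 365, 730, 985), depth = 1000,
                 purity = 0.9, mutsPerClone = 6L, seed = 21L)
sim   <- simulateClonalDynamics(cfg)
paths <- writeSimulation(sim, "demo")
writeLines(c(paste("mutations =", paths[["mutations"]]),
             paste("segments =", paths[["segments"]]),
             paste("samples =", paths[["samples"]]),
             "seed = 21"), "demo/run.cfg")
rep <- runPipeline("demo/run.cfg", outDir = "demo/out")
rep@tree
as.data.frame(rep@fits)
```

which prints

```
CloneTree over 2 clusters (constraints satisfied)
  parent map: 0 1
  posterior constraint mass: 0.193
  newick: ((C2)C1)germline;
  clone     method rate_per_day rate_uncertainty rate_is_lower_bound       n0
1    C1 regression      -0.0021         0.013242               FALSE 1.01e+11
2    C2 regression       0.0187         0.000203               FALSE 1.26e+06
  n0_ci_low n0_ci_high one_in_n_at_day0 n_points status
1  8.76e+10   5.32e+12               NA        3     ok
2  8.71e+05   1.76e+06            79219        3     ok
```

Read: the bulk clone's decline is recovered as −0.21%/day (truth
−0.2%/day) and the resistant clone's growth as 1.87%/day (truth 1.9%/day);
its back-extrapolated size at therapy start is 1.26 × 10⁶ cells (95% CI
0.87–1.76 × 10⁶, truth 10⁶), i.e. about 1 in 79,000 of the circulating CLL
cells on day 0. `demo/out/` contains the CCF, cluster, kinetics and
trajectory tables plus the tree as JSON and Newick.

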