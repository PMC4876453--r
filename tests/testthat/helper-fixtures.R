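## shared fixture builders (everything generated in code)

## mutation observations for clusters at fixed CCF centres:
## centers is clusters x samples; returns a computeCCF() experiment plus
## the true assignment
makeClusterData <- function(centers, nPerCluster = 20L, depth = 1000L,
                            purity = 0.9, seed = 1L) {
  set.seed(seed)
  k <- nrow(centers); ns <- ncol(centers)
  nm <- k * nPerCluster
  assignment <- rep(seq_len(k), each = nPerCluster)
  rows <- list()
  for (s in seq_len(ns)) {
    af <- purity * centers[assignment, s] / (purity * 2 + (1 - purity) * 2)
    dp <- pmax(1L, rpois(nm, depth))
    alt <- rbinom(nm, dp, pmin(1, af))
    rows[[s]] <- data.frame(
      mutation = sprintf("m%03d", seq_len(nm)),
      chrom = "1", pos = seq_len(nm), ref = "A", alt = "T",
      sample = sprintf("S%02d", s),
      t_alt_count = alt, t_ref_count = dp - alt)
  }
  muts <- do.call(rbind, rows)
  samples <- data.frame(sample = sprintf("S%02d", seq_len(ns)),
                        day = seq(0, by = 365, length.out = ns),
                        purity = purity,
                        alc_per_ul = 2000)
  list(se = computeCCF(muts, samples), assignment = assignment,
       muts = muts, samples = samples)
}

## accuracy of an inferred clustering against truth, mapping each inferred
## cluster to its majority true cluster (robust to k mismatch)
assignmentAccuracy <- function(inferred, truth) {
  mapped <- vapply(seq_along(inferred), function(i) {
    members <- which(inferred == inferred[i])
    tab <- table(truth[members])
    as.integer(names(tab)[which.max(tab)])
  }, 0L)
  mean(mapped == truth)
}

## a random rooted tree instance with consistent CCFs:
## exclusive fractions drawn per sample and summed to inclusive
randomTreeInstance <- function(k, ns = 2L, seed = 1L) {
  set.seed(seed)
  parent <- c(0L, vapply(seq_len(k - 1L), function(i) sample.int(i, 1L), 0L))
  excl <- matrix(0, k, ns)
  for (s in seq_len(ns)) {
    w <- rgamma(k, shape = 1) + 0.15      # keep fractions off the boundary
    excl[, s] <- w / sum(w)
  }
  incl <- excl
  for (i in rev(seq_len(k))) {
    kids <- which(parent == i)
    if (length(kids)) incl[i, ] <- excl[i, ] + colSums(incl[kids, , drop = FALSE])
  }
  list(parent = parent, inclusive = incl, exclusive = excl)
}

## paper-like three-clone patient: declining trunk and two rare resistant
## subclones expanding under treatment
paperScenario <- function(seed = 1L) {
  SimConfig(nClones = 3L, parent = c(0L, 1L, 1L),
            initialSizes = c(1e11, 3e6, 2.7e4),
            ratesPerDay = c(-0.002, 0.015, 0.019),
            sampleDays = c(0, 365, 730, 985),
            depth = 1000, purity = 0.9, mutsPerClone = 5L, seed = seed)
}

## run the truth-cluster kinetics recovery for one seed; returns a
## data.frame of per-clone rate estimates, CIs and N0
recoverRates <- function(seed, mcDraws = 400L) {
  cfg <- paperScenario(seed)
  sim <- simulateClonalDynamics(cfg)
  obs <- simulateSequencing(sim)
  se <- computeCCF(obs, as.data.frame(sim@sampleMeta))
  cl <- clustersFromAssignments(se, as.integer(sim@mutations$clone))
  tree <- cloneTreeFromParent(cfg@parent, cl)
  kin <- cloneGrowthFits(tree, as.data.frame(sim@sampleMeta), cl,
                         mcDraws = mcDraws, seed = seed)
  tab <- as.data.frame(kin$table)
  tab$g_true <- cfg@ratesPerDay
  tab$n0_true <- cfg@initialSizes
  tab$ci_low <- vapply(seq_len(nrow(tab)), function(i) {
    f <- kin$fits[[tab$clone[i]]]
    if (is.null(f)) NA_real_ else f@rateCI[1]
  }, 0)
  tab$ci_high <- vapply(seq_len(nrow(tab)), function(i) {
    f <- kin$fits[[tab$clone[i]]]
    if (is.null(f)) NA_real_ else f@rateCI[2]
  }, 0)
  tab
}
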