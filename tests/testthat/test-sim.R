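test_that("clonal dynamics follow the closed-form exponential model", {
  ## one static clone: 1e10 cells in 5 l -> ALC 2000 per ul at every day
  cfg <- SimConfig(nClones = 1L, parent = 0L, initialSizes = 1e10,
                   ratesPerDay = 0, sampleDays = c(0, 100, 400))
  sim <- simulateClonalDynamics(cfg)
  expect_equal(sim@alcPerUl, rep(2000, 3))
  expect_equal(unname(sim@inclusiveCCF[1, ]), rep(1, 3))

  ## slow decline: N(350)/N(0) = exp(-0.7)
  cfg <- SimConfig(nClones = 1L, parent = 0L, initialSizes = 1e10,
                   ratesPerDay = -0.002, sampleDays = c(0, 350))
  sim <- simulateClonalDynamics(cfg)
  expect_equal(sim@cellCounts[1, 2] / sim@cellCounts[1, 1], exp(-0.7),
               tolerance = 1e-12)

  ## default resistant-clone rates sit in the observed 1.5-1.9%/day window
  expect_true(all(SimConfig()@ratesPerDay[-1] >= 0.015 &
                    SimConfig()@ratesPerDay[-1] <= 0.019))
})

test_that("exclusive clone counts conserve the total circulating burden", {
  sim <- simulateClonalDynamics(paperScenario())
  totals <- colSums(sim@cellCounts)
  expect_equal(unname(totals),
               sim@alcPerUl * sim@config@bloodVolumeL * 1e6)
  ## inclusive CCF of a clone = its exclusive cells + descendants, over total
  incl2 <- sim@cellCounts[2, ] / totals                # leaf clone
  expect_equal(unname(sim@inclusiveCCF[2, ]), unname(incl2))
  incl1 <- colSums(sim@cellCounts) / totals            # trunk covers all
  expect_equal(unname(sim@inclusiveCCF[1, ]), unname(incl1))
})

test_that("invalid simulation configs are rejected", {
  expect_error(SimConfig(nClones = 2L, parent = c(2L, 1L),
                         initialSizes = c(1, 1), ratesPerDay = c(0, 0)),
               "cycle|root")
  expect_error(SimConfig(nClones = 1L, parent = 0L, initialSizes = 0,
                         ratesPerDay = 0), "positive")
  expect_error(SimConfig(sampleDays = c(10, 5)), "increasing")
  expect_error(SimConfig(purity = 0), "purity")
  sim <- simulateClonalDynamics(SimConfig())
  expect_error(simulateSequencing(sim, depth = 0), "depth")
  expect_error(simulateAssayData(sim, nCellsScreened = 0), "nCellsScreened")
})

test_that("growth is monotone in the rate", {
  for (g in c(-0.01, 0, 0.01, 0.03)) {
    cfg <- SimConfig(nClones = 1L, parent = 0L, initialSizes = 1e8,
                     ratesPerDay = g, sampleDays = c(0, 200))
    ratio <- with(list(s = simulateClonalDynamics(cfg)),
                  s@cellCounts[1, 2] / s@cellCounts[1, 1])
    if (g > 0) expect_gt(ratio, 1) else if (g < 0) expect_lt(ratio, 1)
    if (exists("lastRatio")) expect_gt(ratio, lastRatio)
    lastRatio <- ratio
  }
})

test_that("simulated read counts match the allele-fraction model", {
  ## clonal het mutation in a pure diploid sample: E[af] = 0.5
  cfg <- SimConfig(nClones = 1L, parent = 0L, initialSizes = 1e10,
                   ratesPerDay = 0, sampleDays = 0, purity = 1,
                   depth = 2000, mutsPerClone = 200L, seed = 7L)
  obs <- simulateSequencing(simulateClonalDynamics(cfg))
  af <- obs$t_alt_count / (obs$t_alt_count + obs$t_ref_count)
  expect_equal(mean(af), 0.5, tolerance = 0.01)

  ## CCF 0.5 at purity 0.8: E[af] = 0.2; depth 1000 keeps af within
  ## 0.2 +/- 0.04 for at least 95% of mutations
  cfg <- SimConfig(nClones = 2L, parent = c(0L, 1L), initialSizes = c(5e9, 5e9),
                   ratesPerDay = c(0, 0), sampleDays = 0, purity = 0.8,
                   depth = 1000, mutsPerClone = 200L, seed = 8L)
  sim <- simulateClonalDynamics(cfg)
  expect_equal(unname(sim@inclusiveCCF[2, 1]), 0.5)
  obs <- simulateSequencing(sim)
  sub <- obs[obs$clone == 2L, ]
  af <- sub$t_alt_count / (sub$t_alt_count + sub$t_ref_count)
  expect_equal(mean(af), 0.2, tolerance = 0.01)
  expect_gte(mean(abs(af - 0.2) <= 0.04), 0.95)
})

test_that("a zero-CCF mutation draws no alt reads without an error model", {
  ## clone 2 extinct at the sampled day (relative size ~ 0)
  cfg <- SimConfig(nClones = 2L, parent = c(0L, 1L),
                   initialSizes = c(1e10, 1), ratesPerDay = c(0, -0.05),
                   sampleDays = c(0, 400), mutsPerClone = 50L, seed = 3L)
  sim <- simulateClonalDynamics(cfg)
  obs <- simulateSequencing(sim)
  late <- obs[obs$clone == 2L & obs$day == 400, ]
  expect_true(all(late$t_alt_count == 0))
  ## with a per-base error rate, alt reads appear at roughly depth x error
  obsErr <- simulateSequencing(sim, errorRate = 1e-2, seed = 3L)
  lateErr <- obsErr[obsErr$clone == 2L & obsErr$day == 400, ]
  expect_gt(sum(lateErr$t_alt_count), 0)
})

test_that("simulation output is deterministic given the seed", {
  sim <- simulateClonalDynamics(paperScenario(11L))
  a <- simulateSequencing(sim, seed = 42L)
  b <- simulateSequencing(sim, seed = 42L)
  expect_identical(a, b)
  c <- simulateSequencing(sim, seed = 43L)
  expect_false(identical(a, c))
  d1 <- simulateAssayData(sim, seed = 5L)
  d2 <- simulateAssayData(sim, seed = 5L)
  expect_identical(d1, d2)
})

test_that("assay simulation reproduces Poisson-scale positive counts", {
  sim <- simulateClonalDynamics(SimConfig(nClones = 1L, parent = 0L,
                                          initialSizes = 1e10, ratesPerDay = 0,
                                          sampleDays = 0))
  ## zero prevalence -> zero positives
  z <- simulateAssayData(sim, prevalence = 0, nCellsScreened = 1e5, seed = 1L)
  expect_identical(z$droplets$n_positive, 0L)
  ## prevalence 1e-4 over 1e6 cells: ~100 positives, within the Poisson
  ## 99% band, across seeds
  band <- qpois(c(0.005, 0.995), 100)
  for (s in 1:5) {
    d <- simulateAssayData(sim, prevalence = 1e-4, nCellsScreened = 1e6,
                           seed = s)
    expect_gte(d$droplets$n_positive, band[1])
    expect_lte(d$droplets$n_positive, band[2])
  }
  ## the study's rarest detected clone: 1 in 500,000 cells
  r <- simulateAssayData(sim, prevalence = 2e-6, nCellsScreened = 5e6, seed = 2L)
  expect_lte(r$droplets$n_positive, qpois(0.995, 10))
})
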