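test_that("Poisson occupancy and its inverse are exact and compose", {
  expect_equal(poissonOccupancy(0), 0)
  expect_equal(poissonOccupancy(log(2)), 0.5)
  ## the <30% loading rule corresponds to lambda < -ln(0.7)
  expect_equal(occupancyToLambda(0.3), -log(0.7), tolerance = 1e-12)
  lam <- seq(0, 5, by = 0.01)
  expect_equal(occupancyToLambda(poissonOccupancy(lam)), lam, tolerance = 1e-12)
  occ <- seq(0, 0.99, by = 0.01)
  expect_equal(poissonOccupancy(occupancyToLambda(occ)), occ, tolerance = 1e-12)
  expect_error(poissonOccupancy(-0.1), "lambda")
  expect_error(occupancyToLambda(1), "occupancy")
})

test_that("rare-cell frequencies carry exact binomial intervals", {
  ## zero positives in a million cells
  z <- estimateMutantFrequency(0, 1e6)
  expect_equal(z$frequency, 0)
  expect_equal(z$ciLow, 0)
  expect_equal(z$ciHigh, 1 - 0.025^(1e-6), tolerance = 1e-9)
  expect_equal(z$ciHigh, 3.6889e-6, tolerance = 1e-4)

  expect_equal(estimateMutantFrequency(3, 2e6)$frequency, 1.5e-6)
  expect_equal(estimateMutantFrequency(10, 10)$frequency, 1)
  expect_equal(estimateMutantFrequency(10, 10)$ciHigh, 1)

  ## agreement with the exact binomial test across representative counts
  for (x in c(1, 5, 100)) {
    n <- 1e5
    ours <- estimateMutantFrequency(x, n)
    ref <- binom.test(x, n)$conf.int
    expect_equal(ours$ciLow, ref[1], tolerance = 1e-10)
    expect_equal(ours$ciHigh, ref[2], tolerance = 1e-10)
  }
  expect_error(estimateMutantFrequency(5, 4), "nPositive")
  expect_error(estimateMutantFrequency(1, 0), "cellsScreened")
})

test_that("frequency intervals achieve near-nominal coverage for rare events", {
  ## exact coverage by enumeration over the achievable counts
  n <- 1e6
  for (f in c(1e-4, 1e-5)) {
    xs <- 0:qpois(1 - 1e-9, n * f)
    hit <- vapply(xs, function(x) {
      ci <- estimateMutantFrequency(x, n)
      ci$ciLow <= f && f <= ci$ciHigh
    }, TRUE)
    coverage <- sum(dbinom(xs[hit], n, f))
    expect_gte(coverage, 0.95)           # Clopper-Pearson is conservative
  }
})

test_that("standard-curve quantification inverts the fitted power law", {
  ## the dilution series used for rare-clone validation: 1 in 1e4/1e5/1e6
  freqs <- c(1e-4, 1e-5, 1e-6)
  signals <- 5000 * freqs^0.8          # perfect power law
  ## a signal equal to a curve point returns that point's input
  est <- standardCurveQuantify(freqs, signals, signals[2])
  expect_equal(est$frequency, 1e-5, tolerance = 1e-9)
  expect_false(est$extrapolated)
  ## midway in log space between the 1e-5 and 1e-6 points: ~3.16e-6
  mid <- exp(mean(log(signals[2:3])))
  est <- standardCurveQuantify(freqs, signals, mid)
  expect_equal(est$frequency, 10^-5.5, tolerance = 1e-9)
  ## beyond the curve range is flagged
  est <- standardCurveQuantify(freqs, signals, max(signals) * 100)
  expect_true(est$extrapolated)
  expect_error(standardCurveQuantify(c(1e-5, 1e-5), c(1, 2), 1), "distinct")
})

test_that("the background regression recovers the negative-cell signal", {
  ## all-zero mutant signal: zero background line
  bg <- fitBackgroundModel(rnorm(50, 1, 0.1), rep(0, 50))
  expect_equal(bg$slope, 0)
  expect_equal(bg$intercept, 0)
  expect_equal(bg$predict(2), 0)

  ## slope 0.05 with noise sd 0.01 at n = 100: recovered within 0.01
  set.seed(23)
  x <- rnorm(100, 1, 0.3)
  y <- 0.05 * x + rnorm(100, 0, 0.01)
  bg <- fitBackgroundModel(x, y)
  expect_equal(bg$slope, 0.05, tolerance = 0.2)
  expect_lte(abs(bg$slope - 0.05), 0.01)
  expect_lte(bg$residualSd, 0.02)

  ## constant offset only: slope 0, intercept = offset
  bg <- fitBackgroundModel(rep(1, 10), rep(0.07, 10))
  expect_equal(bg$slope, 0)
  expect_equal(bg$intercept, 0.07)

  expect_error(fitBackgroundModel(c(1, 2), c(0, 0)), ">= 3")
})

test_that("genotype thresholds partition the mutant-allele fraction exactly", {
  ## direct fractional levels (no background): f = mutant/(normal+mutant)
  call <- function(f) callSingleCellGenotype(f, 1 - f)
  expect_identical(call(0.10), "normal")
  expect_identical(call(0.40), "mutant")
  expect_identical(call(0.15), "unclear")     # boundaries are unclear
  expect_identical(call(0.30), "unclear")
  expect_identical(call(0.2), "unclear")
  expect_identical(callSingleCellGenotype(NA, NA), "excluded")
  expect_identical(callSingleCellGenotype(0, 0), "excluded")
  expect_error(callSingleCellGenotype(-1, 1), "non-negative")

  ## deterministic partition of [0, 1]
  f <- seq(0, 1, by = 0.001)
  calls <- callSingleCellGenotype(f, 1 - f)
  expect_identical(unique(calls[f < 0.15]), "normal")
  expect_identical(unique(calls[f > 0.3 & f < 1]), "mutant")
  expect_identical(unique(calls[f >= 0.15 & f <= 0.3]), "unclear")
  ## f = 1 has normal = 0 but mutant > 0: still mutant, not excluded
  expect_identical(calls[f == 1], "mutant")
})

test_that("background correction rescues borderline normal cells", {
  set.seed(2)
  bg <- fitBackgroundModel(rnorm(100, 1, 0.1), rnorm(100, 0.2, 0.005))
  ## raw f = 0.2/(1 + 0.2) = 0.167 would be unclear; corrected ~ 0 -> normal
  expect_identical(callSingleCellGenotype(0.2, 1, bg), "normal")
  ## strong mutant signal survives correction
  expect_identical(callSingleCellGenotype(1, 1, bg), "mutant")
})

test_that("technical replicates are consolidated by averaging", {
  sig <- data.frame(cell = c("a", "a", "b", "b"),
                    mutant_level = c(0.2, 0.4, NA, 0.6),
                    normal_level = c(1, 1.2, 0.8, NA))
  out <- consolidateReplicates(sig)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mutant_level[out$cell == "a"], 0.3)
  expect_equal(out$normal_level[out$cell == "a"], 1.1)
  expect_equal(out$mutant_level[out$cell == "b"], 0.6)
  expect_equal(out$normal_level[out$cell == "b"], 0.8)
})

test_that("simulated assay data flow through the callers end to end", {
  sim <- simulateClonalDynamics(SimConfig(nClones = 2L, parent = c(0L, 1L),
                                          initialSizes = c(7e9, 3e9),
                                          ratesPerDay = c(0, 0),
                                          sampleDays = 0, seed = 5L))
  a <- simulateAssayData(sim, clone = 2L, nSingleCells = 500L, seed = 5L)
  ## droplet frequency estimate covers the true prevalence (0.3)
  est <- estimateMutantFrequency(a$droplets$n_positive,
                                 a$droplets$cells_screened)
  expect_lte(est$ciLow, 0.3); expect_gte(est$ciHigh, 0.3)
  ## single-cell calls track the simulated truth
  bg <- fitBackgroundModel(a$cells$normal_level[a$cells$truth == "normal"],
                           a$cells$mutant_level[a$cells$truth == "normal"])
  calls <- callSingleCellGenotype(a$cells$mutant_level, a$cells$normal_level, bg)
  agree <- calls[calls %in% c("normal", "mutant")] ==
    a$cells$truth[calls %in% c("normal", "mutant")]
  expect_gte(mean(agree), 0.95)
})
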