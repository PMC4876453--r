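test_that("ALC converts to total circulating cells", {
  expect_equal(totalCllCells(0), 0)
  expect_equal(totalCllCells(1800), 9e9)        # a normal ALC at 5 l
  expect_equal(totalCllCells(20000), 1e11)
  expect_equal(totalCllCells(2000, bloodVolumeL = 4), 8e9)
  expect_error(totalCllCells(-1), "non-negative")
})

test_that("undetected clones are capped at a fraction of the total", {
  expect_equal(undetectedUpperBound(20000), 1e9)          # 1% of 1e11
  expect_equal(undetectedUpperBound(0), 0)
  expect_equal(undetectedUpperBound(2000, boundFraction = 0.05), 5e8)
  expect_error(undetectedUpperBound(2000, boundFraction = 0), "boundFraction")
  expect_error(undetectedUpperBound(2000, boundFraction = 1), "boundFraction")
})

test_that("clone fractions convert to absolute counts", {
  tree <- cloneTreeFromParent(c(0L, 1L), matrix(c(1, 1, 0.5, 0), 2, 2,
                                                byrow = TRUE))
  meta <- data.frame(sample = c("S01", "S02"), day = c(0, 100),
                     alc_per_ul = c(1800, 2000))
  traj <- cloneCellCounts(tree, meta, mode = "inclusive")
  expect_equal(traj$cells[traj$clone == "C2" & traj$day == 0], 4.5e9)
  expect_equal(traj$cells[traj$clone == "C1" & traj$day == 100], 1e10)
  expect_equal(traj$cells[traj$clone == "C2" & traj$day == 100], 0)
  expect_false(traj$detected[traj$clone == "C2" & traj$day == 100])
  expect_error(cloneCellCounts(tree, meta[1, ]), "missing ALC|one row")
})

test_that("two-point rate fits use the exact closed form", {
  fit <- fitGrowthRate(c(0, 100), c(1e4, 1e4 * exp(1.5)))
  expect_equal(fit@rate, 0.015, tolerance = 1e-12)
  expect_identical(fit@method, "two_point")

  expect_equal(fitGrowthRate(c(50, 300), c(777, 777))@rate, 0)

  ## four noiseless points on an exact exponential: slope to 1e-12
  days <- c(0, 200, 500, 900)
  fit <- fitGrowthRate(days, 2e5 * exp(0.033 * days))
  expect_equal(fit@rate, 0.033, tolerance = 1e-12)
  expect_equal(fit@n0, 2e5, tolerance = 1e-9)
  expect_identical(fit@method, "regression")
  expect_equal(fit@rateUncertainty, 0, tolerance = 1e-10)
})

test_that("two-point formula and OLS on two points agree to 1e-12", {
  set.seed(17)
  for (i in 1:50) {
    t1 <- runif(1, 0, 500); t2 <- t1 + runif(1, 10, 800)
    n1 <- 10^runif(1, 2, 11); n2 <- 10^runif(1, 2, 11)
    closed <- log(n2 / n1) / (t2 - t1)
    fit <- fitGrowthRate(c(t1, t2), c(n1, n2))
    expect_equal(fit@rate, closed, tolerance = 1e-12)
  }
})

test_that("monotonicity: inflating the final count never lowers the rate", {
  set.seed(31)
  for (i in 1:20) {
    days <- sort(sample(0:1000, sample(3:5, 1)))
    counts <- exp(runif(1, 5, 20) + runif(1, -0.003, 0.03) * days +
                    rnorm(length(days), 0, 0.2))
    f1 <- fitGrowthRate(days, counts)
    counts2 <- counts; counts2[length(counts2)] <- counts2[length(counts2)] * 2
    f2 <- fitGrowthRate(days, counts2)
    expect_gte(f2@rate, f1@rate)
  }
})

test_that("shared-rate fits give parallel lines in the log domain", {
  days <- c(0, 150, 400, 700)
  gTrue <- 0.02
  counts <- rbind(
    data.frame(clone = "A", day = days, cells = 1e6 * exp(gTrue * days)),
    data.frame(clone = "B", day = days, cells = 5e8 * exp(gTrue * days)))
  fits <- fitSharedRate(counts, groups = list(g1 = c("A", "B")))
  expect_equal(fits$A@rate, gTrue, tolerance = 1e-12)
  expect_equal(fits$B@rate, gTrue, tolerance = 1e-12)
  expect_equal(fits$A@n0, 1e6, tolerance = 1e-6)
  expect_identical(fits$A@method, "shared")

  ## a group of one falls back to the individual fit
  f1 <- fitSharedRate(counts[counts$clone == "A", ], groups = list(g = "A"))$A
  f2 <- fitGrowthRate(days, 1e6 * exp(gTrue * days), clone = "A")
  expect_equal(f1@rate, f2@rate, tolerance = 1e-12)

  ## degenerate design: all observations on one day
  bad <- data.frame(clone = c("A", "B"), day = 0, cells = c(1, 2))
  expect_error(fitSharedRate(bad, groups = list(g = c("A", "B"))), ">= 2")
})

test_that("sharing a rate across clones reduces estimation error", {
  days <- c(0, 150, 400, 700)
  gTrue <- 0.02
  set.seed(12)
  errShared <- errIndiv <- numeric(200)
  for (r in 1:200) {
    counts <- rbind(
      data.frame(clone = "A", day = days,
                 cells = 1e6 * exp(gTrue * days + rnorm(4, 0, 0.1))),
      data.frame(clone = "B", day = days,
                 cells = 5e8 * exp(gTrue * days + rnorm(4, 0, 0.1))))
    fits <- fitSharedRate(counts, groups = list(g = c("A", "B")))
    errShared[r] <- (fits$A@rate - gTrue)^2
    fa <- fitGrowthRate(days, counts$cells[counts$clone == "A"])
    fb <- fitGrowthRate(days, counts$cells[counts$clone == "B"])
    errIndiv[r] <- mean(c((fa@rate - gTrue)^2, (fb@rate - gTrue)^2))
  }
  expect_lt(mean(errShared), mean(errIndiv))
})

test_that("a residual clone is recoverable from the ALC series", {
  days <- c(0, 100, 300, 600, 900)
  known <- fitGrowthRate(c(0, 900), c(1e11 * exp(0), 1e11 * exp(-0.002 * 900)))
  ## truth: second clone grows at 4%/day from 1e5 cells
  set.seed(8)
  totalCells <- 1e11 * exp(-0.002 * days) +
    1e5 * exp(0.04 * days + rnorm(5, 0, 0.05) * c(0, 1, 1, 1, 1))
  meta <- data.frame(day = days, alc_per_ul = totalCells / 5e6)
  fit <- fitRateFromALC(meta, list(known), clone = "resistant")
  expect_identical(fit@method, "alc_fit")
  expect_equal(fit@rate, 0.04, tolerance = 0.002)

  ## with no other clones, this is a plain log-linear fit of ALC x V
  alone <- fitRateFromALC(data.frame(day = days,
                                     alc_per_ul = 2000 * exp(0.01 * days)))
  expect_equal(alone@rate, 0.01, tolerance = 1e-10)
  expect_equal(alone@n0, 1e10, tolerance = 1e-6)

  ## nothing left to explain -> explicit signal
  expect_error(fitRateFromALC(data.frame(day = days, alc_per_ul = rep(2000, 5)),
                              list(fitGrowthRate(c(0, 900), c(2e10, 2e10)))),
               "no residual")
})

test_that("back-extrapolation reproduces the closed-form initial size", {
  ## a clone growing at 1.9%/day reaching 5e11 cells at day 985 started
  ## from ~3.7e3 cells
  days <- c(730, 985)
  n985 <- 5e11
  cells <- n985 * exp(0.019 * (days - 985))
  fit <- fitGrowthRate(days, cells)
  expect_equal(fit@rate, 0.019, tolerance = 1e-12)
  expect_equal(fit@n0, 5e11 * exp(-0.019 * 985), tolerance = 1e-9)
  expect_equal(fit@n0, 3.7e3, tolerance = 0.01)
  res <- extrapolateInitialSize(fit, totalCellsDay0 = 1e11,
                                observedDays = days)
  expect_equal(res$oneInN, round(1e11 / fit@n0))

  ## g = 0: N0 is the geometric mean of the observations
  fit0 <- fitGrowthRate(c(100, 350, 600), c(2e5, 8e5, 2e5))
  expect_equal(fit0@rate, 0, tolerance = 1e-12)
  expect_equal(fit0@n0, exp(mean(log(c(2e5, 8e5, 2e5)))), tolerance = 1e-9)
  flat <- fitGrowthRate(c(100, 400), c(3e6, 3e6))
  expect_equal(flat@n0, 3e6, tolerance = 1e-9)

  ## far extrapolation warns
  farFit <- fitGrowthRate(c(2e4, 3e4), c(1e5, 2e5))
  expect_warning(extrapolateInitialSize(farFit, observedDays = c(2e4, 3e4)),
                 "unreliable")
})

test_that("insufficient trajectories are signalled, not fitted", {
  expect_error(fitGrowthRate(0, 1e5), "insufficient")
  expect_error(fitGrowthRate(c(0, 100), c(1e5, 0)), "zero cell count")
  expect_error(fitGrowthRate(c(100, 100), c(1e5, 2e5)), "duplicated")
})

test_that("rates fitted from an upper-bound start are flagged as lower bounds", {
  ## resistant clone undetected at day 0, detected once at day 985:
  ## the fit uses the day-0 cap, so the true rate can only be larger
  incl <- matrix(c(1, 1, 0.001, 0.6), 2, 2, byrow = TRUE)
  tree <- cloneTreeFromParent(c(0L, 1L), incl)
  meta <- data.frame(sample = c("S01", "S02"), day = c(0, 985),
                     alc_per_ul = c(20000, 30000))
  kin <- cloneGrowthFits(tree, meta, useUpperBounds = TRUE)
  f <- kin$fits[["C2"]]
  expect_true(f@rateIsLowerBound)
  expect_equal(f@nPoints, 2L)
  ## bound at day 0 is 1% of 1e11 cells
  expect_equal(exp(f@intercept), 1e9, tolerance = 1e-6)
  tab <- as.data.frame(kin$table)
  expect_true(tab$rate_is_lower_bound[tab$clone == "C2"])
  ## without bounds the same clone is reported as unfittable
  kin2 <- cloneGrowthFits(tree, meta, useUpperBounds = FALSE)
  expect_identical(as.data.frame(kin2$table)$status[2], "insufficient_data")
})

test_that("predicted ALC matches observation for an exact fit", {
  days <- c(0, 200, 600)
  fit <- fitGrowthRate(days, 1e10 * exp(0.005 * days))
  pred <- predictALC(list(fit), days, observedAlc = 2000 * exp(0.005 * days))
  expect_equal(pred$rmseLog, 0, tolerance = 1e-10)
  ## omitting a growing clone degrades the late fit
  growFit <- fitGrowthRate(days, 1e9 * exp(0.02 * days))
  obs <- (1e10 * exp(0.005 * days) + 1e9 * exp(0.02 * days)) / 5e6
  both <- predictALC(list(fit, growFit), days, observedAlc = obs)
  onlyOne <- predictALC(list(fit), days, observedAlc = obs)
  expect_gt(onlyOne$rmseLog, both$rmseLog)
  expect_lt(both$rmseLog, 1e-10)
})

test_that("clone sizes format as fraction, percent and one-in-N", {
  f <- frequencyFormats(1, 5e5)
  expect_equal(f$percent, 2e-4)
  expect_equal(f$oneInN, 5e5)
  f <- frequencyFormats(100, 100)
  expect_equal(f$percent, 100)
  expect_equal(f$oneInN, 1)
  ## the study's median resistant-clone size: 87 million of 1.392e11 cells
  expect_equal(frequencyFormats(8.7e7, 1.392e11)$oneInN, 1600)
  expect_equal(frequencyFormats(0, 10)$oneInN, Inf)
  expect_error(frequencyFormats(2, 1), "cells")
  expect_error(frequencyFormats(1, 0), "totalCells")
})

test_that("posterior Monte-Carlo intervals cover a simulated initial size", {
  ## clone with true N0 = 1e5 growing at 2%/day, observed at 3 days where
  ## its fraction is well above the CCF grid resolution (the grid cannot
  ## represent fractions below ~0.01, so earlier days are uninformative)
  set.seed(6)
  days <- c(500, 700, 900)
  cover <- factor3 <- logical(50)
  for (r in 1:50) {
    cfg <- SimConfig(nClones = 2L, parent = c(0L, 1L),
                     initialSizes = c(1e10, 1e5),
                     ratesPerDay = c(-0.002, 0.02),
                     sampleDays = days, depth = 1000, purity = 0.9,
                     mutsPerClone = 5L, seed = 600L + r)
    sim <- simulateClonalDynamics(cfg)
    obs <- simulateSequencing(sim)
    se <- computeCCF(obs, as.data.frame(sim@sampleMeta))
    cl <- clustersFromAssignments(se, as.integer(sim@mutations$clone))
    tree <- cloneTreeFromParent(cfg@parent, cl)
    kin <- cloneGrowthFits(tree, as.data.frame(sim@sampleMeta), cl,
                           mcDraws = 300L, seed = r)
    f <- kin$fits[["C2"]]
    cover[r] <- !is.null(f) && f@n0CI[1] <= 1e5 && f@n0CI[2] >= 1e5
    factor3[r] <- !is.null(f) && f@n0 >= 1e5 / 3 && f@n0 <= 1e5 * 3
  }
  expect_gte(mean(cover), 0.80)
  expect_gte(mean(factor3), 0.80)
})
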