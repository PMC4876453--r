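## absolute clone sizes and exponential growth/decline kinetics

#' Total circulating CLL cells implied by an ALC
#'
#' `cells = alc_per_ul x blood volume in litres x 10^6 ul/l`. The ALC is
#' treated as entirely leukaemic (see the methods vignette for the optional
#' tumour-fraction multiplier).
#'
#' @param alcPerUl absolute lymphocyte count per microlitre (>= 0).
#' @param bloodVolumeL peripheral blood volume in litres (default 5).
#' @param tumourFraction fraction of lymphocytes that are CLL (default 1).
#' @return Total circulating cells (vectorised over `alcPerUl`).
#' @examples
#' totalCllCells(1800)  # 9e9 cells at 5 l
#' @export
totalCllCells <- function(alcPerUl, bloodVolumeL = 5, tumourFraction = 1) {
  if (any(alcPerUl < 0)) stop("alcPerUl must be non-negative")
  if (bloodVolumeL <= 0) stop("bloodVolumeL must be positive")
  alcPerUl * bloodVolumeL * 1e6 * tumourFraction
}

#' Upper bound on an undetected clone's size
#'
#' Clones whose CCF falls below the detection threshold are capped at a
#' fixed fraction of the total circulating CLL population (by convention 1%
#' of total CLL cells).
#'
#' @inheritParams totalCllCells
#' @param boundFraction cap as a fraction of total cells, in (0, 1).
#' @return Cell-count upper bound.
#' @export
undetectedUpperBound <- function(alcPerUl, boundFraction = 0.01,
                                 bloodVolumeL = 5) {
  if (boundFraction <= 0 || boundFraction >= 1)
    stop("boundFraction must lie in (0, 1)")
  boundFraction * totalCllCells(alcPerUl, bloodVolumeL)
}

#' Absolute per-clone cell counts over time
#'
#' Multiplies each clone's fraction of the cancer (exclusive by default, so
#' clone counts sum to the total; or inclusive CCF) by the total circulating
#' CLL population at each sampled day. 95% intervals transform the 2.5/97.5
#' posterior percentiles of the fraction; for exclusive fractions these are
#' propagated by Monte-Carlo subtraction of the children's draws. A clone is
#' flagged undetected at a day when its point fraction falls below
#' `detectionCCF`, and the 1%-of-total upper bound is reported there.
#'
#' @param tree a [CloneTree-class].
#' @param meta per-sample metadata `data.frame` with columns sample, day,
#'   alc_per_ul (one row per sampled day, matching the tree's sample
#'   columns).
#' @param clusters optional [CloneClusters-class] for posterior-based
#'   intervals; without it the CI columns equal the point estimate.
#' @param mode `"exclusive"` (default) or `"inclusive"`.
#' @param detectionCCF detection threshold on the point fraction (default
#'   0.01).
#' @param upperBoundFraction cap for undetected days (default 0.01).
#' @param bloodVolumeL blood volume in litres.
#' @param mcDraws,seed Monte-Carlo settings for exclusive-fraction
#'   intervals.
#' @return A `DataFrame` with columns clone, sample, day, fraction, cells,
#'   ciLow, ciHigh, detected, upperBoundCells.
#' @export
cloneCellCounts <- function(tree, meta, clusters = NULL,
                            mode = c("exclusive", "inclusive"),
                            detectionCCF = 0.01, upperBoundFraction = 0.01,
                            bloodVolumeL = 5, mcDraws = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  meta <- as.data.frame(meta)
  if (!all(c("day", "alc_per_ul") %in% names(meta)))
    stop("meta needs columns day and alc_per_ul")
  ns <- ncol(tree@inclusive)
  if (nrow(meta) != ns)
    stop("meta must have one row per sample day (", ns, " expected); ",
         "missing ALC for a sampled day")
  k <- nrow(tree@inclusive)
  frac <- if (mode == "exclusive") tree@exclusive else tree@inclusive
  total <- totalCllCells(meta$alc_per_ul, bloodVolumeL)
  ciLow <- ciHigh <- frac
  if (!is.null(clusters)) {
    draws <- drawClusterCCFs(clusters, mcDraws, seed)     # draws x k x ns
    fracDraws <- if (mode == "exclusive") exclusiveDraws(draws, tree@parent) else draws
    for (j in seq_len(k))
      for (s in seq_len(ns)) {
        qs <- quantile(fracDraws[, j, s], c(0.025, 0.975), names = FALSE)
        ciLow[j, s] <- qs[1]; ciHigh[j, s] <- qs[2]
      }
    ## intervals must cover the point estimate
    ciLow <- pmin(ciLow, frac); ciHigh <- pmax(ciHigh, frac)
  }
  labels <- rownames(tree@inclusive) %||% paste0("C", seq_len(k))
  S4Vectors::DataFrame(
    clone = rep(labels, ns),
    sample = rep(meta$sample %||% sprintf("S%02d", seq_len(ns)), each = k),
    day = rep(meta$day, each = k),
    fraction = as.vector(frac),
    cells = as.vector(sweep(frac, 2L, total, "*")),
    ciLow = as.vector(sweep(ciLow, 2L, total, "*")),
    ciHigh = as.vector(sweep(ciHigh, 2L, total, "*")),
    detected = as.vector(frac >= detectionCCF),
    upperBoundCells = rep(upperBoundFraction * total, each = k))
}

## sample cluster inclusive CCFs from their posteriors: draws x k x ns
drawClusterCCFs <- function(clusters, nDraws, seed) {
  set.seed(as.integer(seed))
  k <- clusters@k; ns <- ncol(clusters@centers)
  draws <- array(0, dim = c(nDraws, k, ns))
  for (j in seq_len(k))
    for (s in seq_len(ns)) {
      v <- clusters@clusterLogLik[j, s, ]
      p <- exp(v - logSumExp(v))
      draws[, j, s] <- clusters@grid[sample.int(length(p), nDraws, TRUE, prob = p)]
    }
  draws
}

## exclusive fractions per draw (floored at 0)
exclusiveDraws <- function(draws, parent) {
  out <- draws
  for (i in seq_along(parent)) {
    kids <- which(parent == i)
    if (length(kids))
      out[, i, ] <- draws[, i, ] - apply(draws[, kids, , drop = FALSE], c(1, 3), sum)
  }
  pmax(out, 0)
}

## log-linear slope/intercept, vectorised over rows of a draws matrix
olsLogSlope <- function(days, logCounts) {
  tc <- days - mean(days)
  if (is.matrix(logCounts)) {
    yb <- rowMeans(logCounts)
    slope <- (logCounts %*% tc) / sum(tc^2)
    intercept <- yb - slope * mean(days)
    cbind(slope = as.vector(slope), intercept = as.vector(intercept))
  } else {
    slope <- sum(tc * (logCounts - mean(logCounts))) / sum(tc^2)
    c(slope = slope, intercept = mean(logCounts) - slope * mean(days))
  }
}

#' Fit a constant exponential rate to one clone's trajectory
#'
#' With exactly two detected observations the rate is the closed form
#' `g = ln(N2/N1) / (t2 - t1)` and its s.d. comes from Monte-Carlo
#' resampling of the CCF posteriors (`countDraws`). With more than two, the
#' rate is the ordinary-least-squares slope of `ln(count)` on day and its
#' s.e. is the regression slope standard error. `N0 = exp(intercept)` is the
#' back-extrapolated size at therapy start; its 95% CI (and the rate's
#' percentile CI) come from the Monte-Carlo draws when supplied, else from
#' the regression t-interval.
#'
#' @param days numeric days of the detected observations (>= 2).
#' @param cells positive cell counts at those days.
#' @param countDraws optional draws x length(days) matrix of Monte-Carlo
#'   cell counts (CCF posteriors propagated to counts) used for the
#'   uncertainty; non-positive draws are floored at 1 cell.
#' @param clone label carried into the result.
#' @param method override the method tag.
#' @param rateIsLowerBound set when the earliest point is an upper bound on
#'   the clone's size, so the fitted rate can only underestimate the true
#'   rate.
#' @return A [GrowthFit-class].
#' @examples
#' fitGrowthRate(c(0, 100), c(1e4, 1e4 * exp(1.5)))  # g = 0.015 exactly
#' @export
fitGrowthRate <- function(days, cells, countDraws = NULL, clone = "clone",
                          method = NULL, rateIsLowerBound = FALSE) {
  if (length(days) != length(cells)) stop("days and cells must align")
  if (length(days) < 2L)
    stop("insufficient data: need >= 2 detected observations ",
         "(consider upper bounds or fitRateFromALC)")
  if (any(cells <= 0))
    stop("zero cell count among detected points; use upper bounds instead")
  if (anyDuplicated(days)) stop("degenerate design: duplicated days")
  n <- length(days)
  y <- log(cells)
  fit <- olsLogSlope(days, y)
  g <- fit["slope"]; b <- fit["intercept"]
  if (n == 2L) {
    se <- NA_real_; utype <- "sd"
    method <- method %||% "two_point"
  } else {
    resid <- y - (b + g * days)
    s2 <- sum(resid^2) / (n - 2)
    se <- sqrt(s2 / sum((days - mean(days))^2))
    utype <- "se"
    method <- method %||% "regression"
  }
  rateCI <- c(NA_real_, NA_real_); n0CI <- c(NA_real_, NA_real_)
  unc <- se
  if (!is.null(countDraws)) {
    dm <- olsLogSlope(days, log(pmax(countDraws, 1)))
    unc <- sd(dm[, "slope"])
    utype <- if (n == 2L) "sd" else utype
    rateCI <- quantile(dm[, "slope"], c(0.025, 0.975), names = FALSE)
    n0CI <- quantile(exp(dm[, "intercept"]), c(0.025, 0.975), names = FALSE)
  } else if (n > 2L) {
    tq <- qt(0.975, n - 2)
    rateCI <- c(g - tq * se, g + tq * se)
    seb <- sqrt(s2 * (1 / n + mean(days)^2 / sum((days - mean(days))^2)))
    n0CI <- exp(c(b - tq * seb, b + tq * seb))
  }
  n0 <- exp(b)
  n0CI[1] <- min(n0CI[1], n0, na.rm = FALSE); n0CI[2] <- max(n0CI[2], n0)
  new("GrowthFit", clone = as.character(clone), rate = unname(g),
      rateUncertainty = unname(unc %||% NA_real_), uncertaintyType = utype,
      rateCI = rateCI, intercept = unname(b), n0 = unname(n0), n0CI = n0CI,
      nPoints = n, method = method, rateIsLowerBound = rateIsLowerBound)
}

#' Fit a shared rate across a group of clones
#'
#' Least squares in the log domain with a common slope per group and
#' clone-specific intercepts (parallel lines), as used when sibling clones
#' are assumed to decline or grow at the same rate.
#'
#' @param counts `data.frame` with columns clone, day, cells (detected
#'   positive observations only).
#' @param groups named list mapping a group label to the clone labels that
#'   share a rate; clones not listed are fitted individually.
#' @return Named list of [GrowthFit-class], one per clone (`method`
#'   `"shared"` for grouped clones of group size > 1).
#' @export
fitSharedRate <- function(counts, groups) {
  counts <- as.data.frame(counts)
  fits <- list()
  grouped <- unlist(groups, use.names = FALSE)
  for (gname in names(groups)) {
    members <- groups[[gname]]
    sub <- counts[counts$clone %in% members, ]
    if (nrow(sub) < 2L || length(unique(sub$day)) < 2L)
      stop("group '", gname, "' needs >= 2 observations spanning >= 2 days")
    if (length(members) == 1L) {
      fits[[members]] <- fitGrowthRate(sub$day, sub$cells, clone = members)
      next
    }
    X <- cbind(model.matrix(~ 0 + factor(clone, levels = members), sub), day = sub$day)
    y <- log(sub$cells)
    beta <- qr.solve(X, y)
    g <- beta["day"]
    resid <- y - X %*% beta
    dfres <- nrow(sub) - ncol(X)
    se <- if (dfres > 0) {
      XtXinv <- chol2inv(chol(crossprod(X)))
      sqrt(sum(resid^2) / dfres * XtXinv[ncol(X), ncol(X)])
    } else NA_real_
    for (i in seq_along(members)) {
      b <- beta[i]
      n0 <- exp(b)
      ci <- if (!is.na(se) && dfres > 0) {
        tq <- qt(0.975, dfres); c(g - tq * se, g + tq * se)
      } else c(NA_real_, NA_real_)
      fits[[members[i]]] <- new("GrowthFit", clone = members[i], rate = unname(g),
          rateUncertainty = unname(se), uncertaintyType = "se", rateCI = ci,
          intercept = unname(b), n0 = unname(n0), n0CI = c(n0, n0),
          nPoints = sum(sub$clone == members[i]), method = "shared",
          rateIsLowerBound = FALSE)
    }
  }
  for (cl in setdiff(unique(counts$clone), grouped)) {
    sub <- counts[counts$clone == cl, ]
    fits[[cl]] <- fitGrowthRate(sub$day, sub$cells, clone = cl)
  }
  fits
}

#' Fit a clone's rate from the unexplained ALC residual
#'
#' For a clone with too few direct measurements, the residual circulating
#' population `ALC x V x 10^6 - sum(other clones' predicted counts)` at each
#' ALC day is fitted as a single exponential by least squares in the log
#' domain. Negative residuals are floored at `floorCells` with a warning.
#'
#' @param meta `data.frame` with columns day, alc_per_ul (ALC-only days are
#'   allowed and used).
#' @param otherFits list of [GrowthFit-class] for the already-fitted clones.
#' @param clone label for the residual clone.
#' @param bloodVolumeL blood volume in litres.
#' @param floorCells floor for non-positive residuals (default 1 cell).
#' @return A [GrowthFit-class] with method `"alc_fit"`.
#' @export
fitRateFromALC <- function(meta, otherFits = list(), clone = "residual",
                           bloodVolumeL = 5, floorCells = 1) {
  meta <- as.data.frame(meta)
  total <- totalCllCells(meta$alc_per_ul, bloodVolumeL)
  pred <- rep(0, nrow(meta))
  for (f in otherFits) pred <- pred + exp(f@intercept + f@rate * meta$day)
  resid <- total - pred
  if (all(resid <= 0)) stop("no residual population: all residuals non-positive")
  if (any(resid <= 0)) {
    warning("non-positive ALC residuals floored at ", floorCells, " cells")
    resid <- pmax(resid, floorCells)
  }
  fitGrowthRate(meta$day, resid, clone = clone, method = "alc_fit")
}

#' Back-extrapolated clone size at therapy initiation
#'
#' Returns the fitted `N0 = exp(intercept)` at day 0 with its 95% CI, and
#' when the day-0 total CLL population is supplied, the size expressed as
#' "1 in N of total CLL cells".
#'
#' @param fit a [GrowthFit-class].
#' @param totalCellsDay0 optional total circulating CLL cells at day 0.
#' @param observedDays days of the observations behind the fit; a warning is
#'   issued when day 0 lies more than `maxExtrapolationDays` from the
#'   nearest one.
#' @param maxExtrapolationDays sanity window (default 1e4 days).
#' @return list with `n0`, `ci` and (when available) `oneInN`.
#' @export
extrapolateInitialSize <- function(fit, totalCellsDay0 = NULL,
                                   observedDays = NULL,
                                   maxExtrapolationDays = 1e4) {
  if (!is.finite(fit@rate)) stop("fit has no finite rate")
  if (!is.null(observedDays) && min(abs(observedDays)) > maxExtrapolationDays)
    warning("day 0 is more than ", maxExtrapolationDays,
            " days from the nearest observation; extrapolation is unreliable")
  out <- list(n0 = fit@n0, ci = fit@n0CI)
  if (!is.null(totalCellsDay0))
    out$oneInN <- frequencyFormats(min(fit@n0, totalCellsDay0), totalCellsDay0)$oneInN
  out
}

#' Predicted ALC from fitted clones
#'
#' `ALC(t) = sum_c N0_c exp(g_c t) / (V x 10^6)`; when observed ALCs are
#' supplied the log-domain RMSE is reported as the goodness of fit.
#'
#' @param fits list of [GrowthFit-class] (all clones).
#' @param days days at which to predict.
#' @param bloodVolumeL blood volume in litres.
#' @param observedAlc optional observed ALC per microlitre at `days`.
#' @return list with `day`, `alcPred` and (when observed) `rmseLog`.
#' @export
predictALC <- function(fits, days, bloodVolumeL = 5, observedAlc = NULL) {
  cells <- rep(0, length(days))
  for (f in fits) cells <- cells + exp(f@intercept + f@rate * days)
  pred <- cells / (bloodVolumeL * 1e6)
  out <- list(day = days, alcPred = pred)
  if (!is.null(observedAlc))
    out$rmseLog <- sqrt(mean((log(pred) - log(observedAlc))^2))
  out
}

#' Express a clone size as fraction, percent and "1 in N"
#'
#' @param cells clone size in cells (0 <= cells <= totalCells).
#' @param totalCells total population (> 0).
#' @return list with `fraction`, `percent`, `oneInN` (`oneInN` is `Inf` for
#'   zero cells).
#' @examples
#' frequencyFormats(1, 5e5)  # 0.0002 percent, one in 500,000
#' @export
frequencyFormats <- function(cells, totalCells) {
  if (totalCells <= 0) stop("totalCells must be positive")
  if (cells < 0 || cells > totalCells) stop("cells must lie in [0, totalCells]")
  frac <- cells / totalCells
  list(fraction = frac, percent = 100 * frac,
       oneInN = if (cells > 0) round(totalCells / cells) else Inf)
}

#' Fit growth kinetics for every clone of a tree
#'
#' The orchestration used by [runPipeline()]: converts the tree's fractions
#' to absolute counts, selects each clone's detected observations, fits the
#' exponential rate (two-point closed form or log-domain OLS), and
#' propagates CCF-posterior uncertainty by joint Monte-Carlo: cluster CCFs
#' are resampled from their posteriors, exclusive fractions and counts are
#' recomputed, and the fit repeated per draw. The detected-day set is fixed
#' at the point estimates across draws. Clones whose earliest usable point
#' is an upper-bound entry are flagged as lower-bound rates; clones with
#' fewer than two detected days are reported with status
#' `"insufficient_data"`.
#'
#' @inheritParams cloneCellCounts
#' @param mcDraws Monte-Carlo draws for the uncertainty (default 1000).
#' @param useUpperBounds when TRUE, a clone with exactly one detected day
#'   additionally uses the latest earlier undetected day's upper bound as a
#'   starting point, and the resulting rate is flagged as a lower bound.
#' @return list with `fits` (named list of [GrowthFit-class]), `table`
#'   (`DataFrame`, one row per clone incl. status), and `trajectories` (the
#'   [cloneCellCounts()] output).
#' @export
cloneGrowthFits <- function(tree, meta, clusters = NULL,
                            mode = c("exclusive", "inclusive"),
                            detectionCCF = 0.01, upperBoundFraction = 0.01,
                            bloodVolumeL = 5, mcDraws = 1000L, seed = 1L,
                            useUpperBounds = TRUE) {
  mode <- match.arg(mode)
  meta <- as.data.frame(meta)
  traj <- cloneCellCounts(tree, meta, clusters, mode, detectionCCF,
                          upperBoundFraction, bloodVolumeL, mcDraws, seed)
  k <- nrow(tree@inclusive); ns <- ncol(tree@inclusive)
  labels <- rownames(tree@inclusive) %||% paste0("C", seq_len(k))
  total <- totalCllCells(meta$alc_per_ul, bloodVolumeL)
  fracDraws <- NULL
  if (!is.null(clusters)) {
    draws <- drawClusterCCFs(clusters, mcDraws, seed)
    fracDraws <- if (mode == "exclusive") exclusiveDraws(draws, tree@parent) else draws
  }
  fits <- list(); rows <- list()
  for (j in seq_len(k)) {
    sub <- traj[traj$clone == labels[j], ]
    det <- which(sub$detected & sub$cells > 0)
    lower <- FALSE
    days <- sub$day[det]; cells <- sub$cells[det]; useIdx <- det
    if (length(det) == 1L && useUpperBounds) {
      earlier <- which(!sub$detected & sub$day < min(days))
      if (length(earlier)) {
        u <- earlier[which.max(sub$day[earlier])]
        days <- c(sub$day[u], days)
        cells <- c(sub$upperBoundCells[u], cells)
        useIdx <- c(u, det)
        lower <- TRUE
      }
    }
    if (length(days) < 2L) {
      rows[[j]] <- data.frame(clone = labels[j], method = "none",
                              rate_per_day = NA, rate_uncertainty = NA,
                              rate_is_lower_bound = NA, n0 = NA,
                              n0_ci_low = NA, n0_ci_high = NA,
                              one_in_n_at_day0 = NA, n_points = length(days),
                              status = "insufficient_data")
      next
    }
    cd <- NULL
    if (!is.null(fracDraws) && !lower) {
      cd <- sweep(fracDraws[, j, useIdx, drop = FALSE], 3L,
                  total[useIdx], "*")
      dim(cd) <- c(dim(fracDraws)[1], length(useIdx))
    }
    fit <- fitGrowthRate(days, cells, countDraws = cd, clone = labels[j],
                         rateIsLowerBound = lower)
    fits[[labels[j]]] <- fit
    oneInN <- if (any(meta$day == 0) && fit@n0 <= total[meta$day == 0][1])
      frequencyFormats(fit@n0, total[meta$day == 0][1])$oneInN else NA
    rows[[j]] <- data.frame(clone = labels[j], method = fit@method,
                            rate_per_day = fit@rate,
                            rate_uncertainty = fit@rateUncertainty,
                            rate_is_lower_bound = fit@rateIsLowerBound,
                            n0 = fit@n0, n0_ci_low = fit@n0CI[1],
                            n0_ci_high = fit@n0CI[2],
                            one_in_n_at_day0 = oneInN,
                            n_points = fit@nPoints, status = "ok")
  }
  list(fits = fits, table = S4Vectors::DataFrame(do.call(rbind, rows)),
       trajectories = traj)
}
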