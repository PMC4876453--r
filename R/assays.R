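## statistics of the two rare-cell validation assays

#' Poisson droplet occupancy
#'
#' Under Poisson loading at `lambda` templates per droplet, the fraction of
#' droplets containing at least one template is `1 - exp(-lambda)`.
#' Digital assays are typically loaded so that fewer than 30% of droplets
#' are occupied (lambda below about 0.357), keeping multiple occupancy
#' rare.
#'
#' @param lambda mean templates per droplet (>= 0).
#' @return Occupied fraction in \[0, 1).
#' @seealso [occupancyToLambda()]
#' @export
poissonOccupancy <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  1 - exp(-lambda)
}

#' Loading intensity from droplet occupancy
#'
#' Inverse of [poissonOccupancy()]: `lambda = -log(1 - occupancy)`.
#'
#' @param occupancy occupied droplet fraction in \[0, 1).
#' @return Mean templates per droplet.
#' @export
occupancyToLambda <- function(occupancy) {
  if (any(occupancy < 0 | occupancy >= 1)) stop("occupancy must lie in [0, 1)")
  -log(1 - occupancy)
}

#' Mutant-cell frequency with exact binomial confidence interval
#'
#' Point estimate `n_positive / cells_screened` with the Clopper-Pearson
#' exact 95% interval, appropriate for frequencies down to 10^-6 where
#' normal approximations fail. Zero positives yield the interval
#' \[0, 1 - 0.025^(1/n)\].
#'
#' @param nPositive positive droplets/cells observed.
#' @param cellsScreened cells screened (> 0).
#' @param level confidence level (default 0.95).
#' @return list with `frequency`, `ciLow`, `ciHigh`, `nPositive`,
#'   `cellsScreened`.
#' @examples
#' estimateMutantFrequency(2, 1e6)  # ~ 1 in 500,000
#' @export
estimateMutantFrequency <- function(nPositive, cellsScreened, level = 0.95) {
  if (cellsScreened <= 0) stop("cellsScreened must be positive")
  if (nPositive < 0 || nPositive > cellsScreened)
    stop("nPositive must lie in [0, cellsScreened]")
  a <- (1 - level) / 2
  x <- nPositive; n <- cellsScreened
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  list(frequency = x / n, ciLow = lo, ciHigh = hi,
       nPositive = x, cellsScreened = n)
}

#' Quantify an unknown sample against a dilution standard curve
#'
#' Fits a least-squares line of log signal on log input frequency through
#' the standard-curve points (e.g. spike-ins at 1 in 10^4, 10^5 and 10^6
#' cells) and inverts the observed signal through the fitted line.
#' Estimates falling outside the curve's input range are flagged as
#' extrapolated.
#'
#' @param curveFrequency known input frequencies of the curve points (> 0,
#'   at least two distinct).
#' @param curveSignal observed signals of the curve points (> 0).
#' @param observedSignal signal of the unknown sample (> 0; vectorised).
#' @return list with `frequency`, `extrapolated` (logical), `slope`,
#'   `intercept` (log-log scale).
#' @export
standardCurveQuantify <- function(curveFrequency, curveSignal, observedSignal) {
  if (length(curveFrequency) < 2L || length(unique(curveFrequency)) < 2L)
    stop("need >= 2 curve points with distinct input frequencies")
  if (any(curveFrequency <= 0) || any(curveSignal <= 0) || any(observedSignal <= 0))
    stop("frequencies and signals must be positive")
  fit <- olsLogSlope(log(curveFrequency), log(curveSignal))
  slope <- fit["slope"]; intercept <- fit["intercept"]
  if (abs(slope) < 1e-12) stop("flat standard curve: signal does not vary with input")
  logFreq <- (log(observedSignal) - intercept) / slope
  freq <- exp(logFreq)
  list(frequency = unname(freq),
       extrapolated = freq < min(curveFrequency) | freq > max(curveFrequency),
       slope = unname(slope), intercept = unname(intercept))
}

#' Background model for single-cell mutant-allele signal
#'
#' Regresses the mutant-allele level on the normal-allele level across
#' known-negative (normal B) cells, giving the expected background mutant
#' signal of a truly mutation-free cell, with the residual s.d.
#'
#' @param normalLevel normal-allele signal of the negative cells.
#' @param mutantLevel mutant-allele signal of the same cells.
#' @return list with `slope`, `intercept`, `residualSd`, `n`, and a
#'   `predict(normalLevel)` function.
#' @export
fitBackgroundModel <- function(normalLevel, mutantLevel) {
  keep <- is.finite(normalLevel) & is.finite(mutantLevel)
  normalLevel <- normalLevel[keep]; mutantLevel <- mutantLevel[keep]
  if (length(normalLevel) < 3L) stop("need >= 3 usable negative cells")
  if (var(normalLevel) == 0) {
    slope <- 0; intercept <- mean(mutantLevel)
    resid <- mutantLevel - intercept
  } else {
    slope <- sum((normalLevel - mean(normalLevel)) *
                 (mutantLevel - mean(mutantLevel))) / sum((normalLevel - mean(normalLevel))^2)
    intercept <- mean(mutantLevel) - slope * mean(normalLevel)
    resid <- mutantLevel - (intercept + slope * normalLevel)
  }
  n <- length(normalLevel)
  list(slope = slope, intercept = intercept,
       residualSd = sqrt(sum(resid^2) / max(1, n - 2)), n = n,
       predict = function(x) intercept + slope * x)
}

#' Call single-cell genotypes from allele-specific signals
#'
#' The background-corrected mutant level is
#' `m' = max(0, mutant - predicted background)` and the normalised
#' fractional mutant allele `f = m' / (normal + m')`. Cells with `f` below
#' 0.15 are called normal, above 0.3 mutant, and in the closed interval
#' \[0.15, 0.3\] unclear; cells with neither allele detected (0/0) are
#' excluded. Technical replicates should be consolidated by averaging
#' levels before calling (see [consolidateReplicates()]).
#'
#' @param mutantLevel,normalLevel allele signal vectors (>= 0; `NA` =
#'   not detected).
#' @param background fit from [fitBackgroundModel()]; omit for no
#'   correction.
#' @param lowerThreshold,upperThreshold call thresholds (defaults 0.15 and
#'   0.3).
#' @return Character vector in `{"normal", "mutant", "unclear",
#'   "excluded"}`.
#' @export
callSingleCellGenotype <- function(mutantLevel, normalLevel, background = NULL,
                                   lowerThreshold = 0.15, upperThreshold = 0.3) {
  if (any(mutantLevel < 0, na.rm = TRUE) || any(normalLevel < 0, na.rm = TRUE))
    stop("allele levels must be non-negative")
  m <- ifelse(is.na(mutantLevel), 0, mutantLevel)
  nl <- ifelse(is.na(normalLevel), 0, normalLevel)
  if (!is.null(background)) m <- pmax(0, m - background$predict(nl))
  f <- m / (nl + m)
  out <- rep("unclear", length(f))
  out[is.nan(f)] <- "excluded"                # 0/0: neither allele detected
  out[!is.nan(f) & f < lowerThreshold] <- "normal"
  out[!is.nan(f) & f > upperThreshold] <- "mutant"
  out
}

#' Average technical replicates of single-cell signals
#'
#' @param signals `data.frame` with columns cell, mutant_level,
#'   normal_level (one row per cell per replicate).
#' @return One row per cell with levels averaged across replicates
#'   (`NA`s dropped; all-`NA` stays `NA`).
#' @export
consolidateReplicates <- function(signals) {
  signals <- as.data.frame(signals)
  agg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  out <- aggregate(signals[, c("mutant_level", "normal_level")],
                   by = list(cell = signals$cell), FUN = agg)
  out[order(out$cell), , drop = FALSE]
}
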