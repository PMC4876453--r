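## EM mixture clustering of mutations by multi-sample CCF

## k-means++-style seeding on the point-CCF matrix, then EM with one CCF
## centre per cluster per sample. When read counts are available the centre
## is continuous (weighted binomial maximum likelihood, so the model is not
## limited by the posterior grid resolution); for bare likelihood arrays the
## centre is restricted to the grid.

#' Cluster mutations by their CCF vectors across serial samples
#'
#' Fits a finite mixture by expectation-maximisation for k = 1..`kMax` and
#' selects k by the Bayesian information criterion. Each component is a CCF
#' centre vector (one value per sample); a mutation's component likelihood
#' is the product over samples of its binomial read-count likelihood at the
#' component's centre, through the purity/copy-number allele-fraction model.
#' Initialisation is k-means++-style seeding on the per-mutation point-CCF
#' vectors with `nRestarts` restarts; the best log-likelihood is kept and
#' ties are broken toward lower k, then the earlier restart.
#'
#' @param ccfSE `SummarizedExperiment` from [computeCCF()] (counts and the
#'   `metadata()$logLik` array drive the fit), or a bare mutations x
#'   samples x grid log-likelihood array (centres then live on the grid).
#' @param kMax maximum number of clusters considered (>= 1).
#' @param seed integer seed (initialisation only; the fit is deterministic
#'   given the seed).
#' @param nRestarts EM restarts per k.
#' @param maxIter,tol EM stopping rule (log-likelihood change below `tol`).
#' @param grid CCF grid (required only when `ccfSE` is a bare array).
#' @return A [CloneClusters-class].
#' @export
clusterCCF <- function(ccfSE, kMax = 6L, seed = 1L, nRestarts = 10L,
                       maxIter = 200L, tol = 1e-8, grid = NULL) {
  counts <- NULL
  if (methods::is(ccfSE, "SummarizedExperiment")) {
    ll <- S4Vectors::metadata(ccfSE)$logLik
    grid <- S4Vectors::metadata(ccfSE)$grid
    altM <- SummarizedExperiment::assay(ccfSE, "alt")
    depthM <- altM + SummarizedExperiment::assay(ccfSE, "ref")
    ## af(c) = afCoef * c per mutation and sample
    purity <- SummarizedExperiment::colData(ccfSE)$purity
    q <- if ("totalCn" %in% SummarizedExperiment::assayNames(ccfSE))
      SummarizedExperiment::assay(ccfSE, "totalCn") else matrix(2, nrow(altM), ncol(altM))
    m <- if ("multiplicity" %in% SummarizedExperiment::assayNames(ccfSE))
      SummarizedExperiment::assay(ccfSE, "multiplicity") else matrix(1, nrow(altM), ncol(altM))
    afCoef <- sweep(m, 2L, purity, "*") /
      (sweep(q, 2L, purity, "*") + outer(rep(2, nrow(q)), 1 - purity))
    counts <- list(alt = altM, depth = depthM, afCoef = afCoef)
  } else {
    ll <- ccfSE
    if (is.null(grid)) grid <- defaultGrid(1 / (dim(ll)[3] - 1))
  }
  kMax <- as.integer(kMax)
  if (kMax < 1L) stop("kMax must be >= 1")
  nm <- dim(ll)[1]; ns <- dim(ll)[2]; ng <- dim(ll)[3]
  keys <- dimnames(ll)[[1]] %||% sprintf("m%d", seq_len(nm))
  sids <- dimnames(ll)[[2]] %||% sprintf("S%02d", seq_len(ns))
  pointCCF <- matrix(0, nm, ns)
  for (s in seq_len(ns))
    pointCCF[, s] <- grid[apply(ll[, s, , drop = FALSE], 1L, which.max)]

  ## component log-likelihood of every mutation at a centre vector
  compLLAt <- function(centers) {        # centers: k x ns
    k <- nrow(centers)
    out <- matrix(0, nm, k)
    for (j in seq_len(k))
      for (s in seq_len(ns)) {
        if (!is.null(counts)) {
          af <- pmin(pmax(counts$afCoef[, s] * centers[j, s], 1e-12), 1 - 1e-12)
          out[, j] <- out[, j] + dbinom(counts$alt[, s], counts$depth[, s], af, log = TRUE)
        } else {
          gi <- which.min(abs(grid - centers[j, s]))
          out[, j] <- out[, j] + ll[, s, gi]
        }
      }
    out
  }

  ## weighted maximum-likelihood centre for one cluster in one sample
  centerMLE <- function(resp, s) {
    if (!is.null(counts)) {
      coef <- counts$afCoef[, s]
      if (max(coef) - min(coef) < 1e-12) {
        ## homogeneous copy state: closed-form weighted MLE
        af <- sum(resp * counts$alt[, s]) / max(1e-300, sum(resp * counts$depth[, s]))
        return(min(1, max(0, af / coef[1])))
      }
      f <- function(c) {
        af <- pmin(pmax(coef * c, 1e-12), 1 - 1e-12)
        -sum(resp * dbinom(counts$alt[, s], counts$depth[, s], af, log = TRUE))
      }
      return(optimise(f, c(0, 1), tol = 1e-6)$minimum)
    }
    obj <- colSums(resp * matrix(ll[, s, ], nrow = nm))
    grid[max(which(obj >= max(obj) - 1e-12))]
  }

  fitOne <- function(k, centers) {
    logPi <- rep(log(1 / k), k)
    prev <- -Inf; resp <- NULL
    for (it in seq_len(maxIter)) {
      w <- sweep(compLLAt(centers), 2L, logPi, "+")
      norm <- rowLogSumExp(w)
      resp <- exp(w - norm)
      total <- sum(norm)
      if (is.finite(prev) && abs(total - prev) < tol) break
      prev <- total
      nk <- colSums(resp)
      logPi <- log(pmax(nk, 1e-12) / nm)
      for (j in seq_len(k))
        for (s in seq_len(ns))
          centers[j, s] <- centerMLE(resp[, j], s)
    }
    list(logLik = prev, centers = centers, resp = resp)
  }

  seedPlusPlus <- function(k) {
    ## distance-weighted seeding on point CCF vectors
    idx <- sample.int(nm, 1L)
    while (length(idx) < k) {
      d2 <- apply(pointCCF, 1L, function(x)
        min(colSums((t(pointCCF[idx, , drop = FALSE]) - x)^2)))
      if (all(d2 <= 0)) idx <- c(idx, sample.int(nm, 1L))
      else idx <- c(idx, sample.int(nm, 1L, prob = d2))
    }
    pointCCF[idx, , drop = FALSE]
  }

  set.seed(as.integer(seed))
  best <- NULL
  bics <- setNames(numeric(kMax), paste0("k", seq_len(kMax)))
  for (k in seq_len(kMax)) {
    bestK <- NULL
    for (r in seq_len(if (k == 1L) 1L else nRestarts)) {
      fit <- fitOne(k, seedPlusPlus(k))
      if (is.null(bestK) || fit$logLik > bestK$logLik + 1e-9) bestK <- fit
    }
    npar <- (k - 1) + k * ns
    bics[k] <- -2 * bestK$logLik + npar * log(nm)
    if (is.null(best) || bics[k] < best$bic - 1e-9) {
      best <- bestK; best$bic <- bics[k]; best$k <- k
    }
  }
  k <- best$k
  assignment <- max.col(best$resp, ties.method = "first")
  ## drop empty components (can arise on degenerate data)
  used <- sort(unique(assignment))
  if (length(used) < k) {
    assignment <- match(assignment, used)
    best$resp <- best$resp[, used, drop = FALSE]
    best$centers <- best$centers[used, , drop = FALSE]
    k <- length(used)
  }
  ## cluster posterior: sum member log-likelihoods (grid product posterior)
  clLL <- array(0, dim = c(k, ns, ng), dimnames = list(paste0("C", seq_len(k)), sids, NULL))
  for (j in seq_len(k)) {
    members <- which(assignment == j)
    for (s in seq_len(ns))
      clLL[j, s, ] <- colSums(matrix(ll[members, s, ], nrow = length(members)))
  }
  centers <- best$centers
  ## order clusters by mean CCF (descending): trunk-like first
  ord <- order(-rowMeans(centers))
  assignment <- match(assignment, ord)
  centers <- centers[ord, , drop = FALSE]
  clLL <- clLL[ord, , , drop = FALSE]
  dimnames(centers) <- list(paste0("C", seq_len(k)), sids)
  dimnames(clLL) <- list(paste0("C", seq_len(k)), sids, NULL)
  new("CloneClusters",
      assignment = setNames(as.integer(assignment), keys),
      responsibility = best$resp[, ord, drop = FALSE],
      centers = centers,
      clusterLogLik = clLL,
      grid = grid, logLik = best$logLik, bic = bics, k = as.integer(k))
}

#' Build clusters from known mutation assignments
#'
#' Bypasses the EM fit when the mutation-to-clone assignment is known (for
#' example from an orthogonal assay, or when assessing the downstream
#' stages against simulated truth): cluster posteriors are the grid-wise
#' products of the member posteriors and the centres their modes. Cluster
#' ids follow the order of `sort(unique(assignment))`; no reordering by CCF
#' is applied.
#'
#' @param ccfSE `SummarizedExperiment` from [computeCCF()].
#' @param assignment integer cluster id per mutation (in the row order of
#'   `ccfSE`).
#' @return A [CloneClusters-class] (with `logLik`/`bic` unset).
#' @export
clustersFromAssignments <- function(ccfSE, assignment) {
  ll <- S4Vectors::metadata(ccfSE)$logLik
  grid <- S4Vectors::metadata(ccfSE)$grid
  nm <- dim(ll)[1]; ns <- dim(ll)[2]; ng <- dim(ll)[3]
  if (length(assignment) != nm) stop("one assignment per mutation required")
  keys <- dimnames(ll)[[1]] %||% sprintf("m%d", seq_len(nm))
  sids <- dimnames(ll)[[2]] %||% sprintf("S%02d", seq_len(ns))
  ids <- sort(unique(assignment))
  k <- length(ids)
  assignment <- match(assignment, ids)
  clLL <- array(0, dim = c(k, ns, ng), dimnames = list(paste0("C", seq_len(k)), sids, NULL))
  centers <- matrix(0, k, ns, dimnames = list(paste0("C", seq_len(k)), sids))
  resp <- matrix(0, nm, k)
  resp[cbind(seq_len(nm), assignment)] <- 1
  for (j in seq_len(k)) {
    members <- which(assignment == j)
    for (s in seq_len(ns)) {
      v <- colSums(matrix(ll[members, s, ], nrow = length(members)))
      clLL[j, s, ] <- v
      centers[j, s] <- grid[max(which(v >= max(v) - 1e-12))]
    }
  }
  new("CloneClusters", assignment = setNames(as.integer(assignment), keys),
      responsibility = resp, centers = centers, clusterLogLik = clLL,
      grid = grid, logLik = NA_real_, bic = NA_real_, k = as.integer(k))
}

#' Posterior CCF of one cluster in one sample
#'
#' The cluster posterior is the grid-wise product of its member mutations'
#' posteriors (equivalently, the normalised sum of their log-likelihoods
#' under a uniform prior); with concordant members it is sharper than any
#' single member's posterior.
#'
#' @param clusters a [CloneClusters-class].
#' @param cluster cluster index (1..k).
#' @param sample sample index or name.
#' @return A [CCFPosterior-class].
#' @export
clusterCCFPosterior <- function(clusters, cluster, sample) {
  if (clusters@k < 1L || cluster < 1L || cluster > clusters@k)
    stop("cluster index out of range")
  if (is.character(sample)) sample <- match(sample, colnames(clusters@centers))
  if (!sum(clusters@assignment == cluster))
    stop("cluster has no member mutations")
  v <- clusters@clusterLogLik[cluster, sample, ]
  probs <- exp(v - logSumExp(v))
  new("CCFPosterior", grid = clusters@grid, probs = probs / sum(probs))
}
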