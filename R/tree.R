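## clone tree inference from cluster CCFs under lineage (pigeonhole)
## constraints: exhaustive enumeration of rooted trees, Monte-Carlo scoring
## against the cluster CCF posteriors, exclusive-fraction accounting

## constraint violation of a parent map given inclusive CCFs (k x S):
## crossing rule  : child inclusive CCF must not exceed its parent's
## pigeonhole rule: a parent must cover the sum of its children
treeViolation <- function(parent, inclusive) {
  k <- nrow(inclusive)
  v <- 0
  for (s in seq_len(ncol(inclusive))) {
    ccf <- inclusive[, s]
    for (i in seq_len(k)) {
      p <- parent[i]
      pc <- if (p == 0L) 1 else ccf[p]
      v <- v + max(0, ccf[i] - pc)
    }
    for (p in seq_len(k)) {
      kids <- which(parent == p)
      if (length(kids)) v <- v + max(0, sum(ccf[kids]) - ccf[p])
    }
    kidsRoot <- which(parent == 0L)
    v <- v + max(0, sum(ccf[kidsRoot]) - 1)
  }
  v
}

treeSatisfies <- function(parent, inclusive, epsilon) {
  k <- nrow(inclusive)
  for (s in seq_len(ncol(inclusive))) {
    ccf <- inclusive[, s]
    for (i in seq_len(k)) {
      p <- parent[i]
      pc <- if (p == 0L) 1 else ccf[p]
      if (ccf[i] > pc + epsilon) return(FALSE)
    }
    for (p in seq_len(k)) {
      kids <- which(parent == p)
      if (length(kids) && sum(ccf[kids]) > ccf[p] + epsilon) return(FALSE)
    }
  }
  TRUE
}

## all parent maps rooted at `trunk` over k nodes (trunk has parent 0)
allParentMaps <- function(k, trunk) {
  others <- setdiff(seq_len(k), trunk)
  if (!length(others)) return(list(setNames(0L, NULL)))
  choices <- lapply(others, function(i) setdiff(seq_len(k), i))
  gridIdx <- do.call(expand.grid, choices)
  out <- list()
  for (r in seq_len(nrow(gridIdx))) {
    parent <- integer(k)
    parent[trunk] <- 0L
    parent[others] <- as.integer(gridIdx[r, ])
    ## reject maps with cycles (nodes not reaching the trunk)
    ok <- TRUE
    for (i in others) {
      seen <- integer(); node <- i
      while (node != 0L) {
        if (node %in% seen) { ok <- FALSE; break }
        seen <- c(seen, node); node <- parent[node]
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- parent
  }
  out
}

newCloneTree <- function(parent, inclusive, valid, epsilon) {
  excl <- exclusiveFromInclusive(parent, inclusive)
  new("CloneTree", parent = as.integer(parent), inclusive = inclusive,
      exclusive = excl$fractions, score = NA_real_, valid = valid,
      violation = treeViolation(parent, inclusive),
      clipMagnitude = excl$clipMagnitude)
}

exclusiveFromInclusive <- function(parent, inclusive) {
  excl <- inclusive
  for (i in seq_len(nrow(inclusive))) {
    kids <- which(parent == i)
    if (length(kids))
      excl[i, ] <- inclusive[i, ] - colSums(inclusive[kids, , drop = FALSE])
  }
  clip <- sum(pmax(0, -excl))
  list(fractions = pmax(excl, 0), clipMagnitude = clip)
}

#' Enumerate all clone trees consistent with cluster CCFs
#'
#' Considers every rooted tree over the clusters whose trunk is the clonal
#' cluster (CCF >= 1 - `epsilon` in all samples, attached to the germline
#' root) and keeps those satisfying, in every sample, (i) the crossing rule
#' -- a child's inclusive CCF may not exceed its parent's by more than
#' `epsilon` -- and (ii) the pigeonhole rule -- the children of a node may
#' not sum to more than the node's CCF plus `epsilon`.
#'
#' @param clusters a [CloneClusters-class], or a bare clusters x samples
#'   matrix of point CCFs.
#' @param epsilon constraint tolerance on point CCFs (default 0.10, sized to
#'   absorb binomial noise at moderate depth).
#' @param maxClusters guard on the exhaustive enumeration (default 8).
#' @return List of [CloneTree-class] candidates (possibly empty).
#' @export
enumerateValidTrees <- function(clusters, epsilon = 0.10, maxClusters = 8L) {
  inclusive <- if (methods::is(clusters, "CloneClusters")) clusters@centers else clusters
  k <- nrow(inclusive)
  if (k > maxClusters)
    stop("exhaustive enumeration limited to ", maxClusters, " clusters")
  trunkCand <- which(apply(inclusive, 1L, function(x) all(x >= 1 - epsilon)))
  if (!length(trunkCand))
    stop("no trunk cluster: no cluster has CCF >= 1 - epsilon in every sample")
  trunk <- trunkCand[which.max(rowMeans(inclusive)[trunkCand])]
  maps <- allParentMaps(k, trunk)
  keep <- Filter(function(p) treeSatisfies(p, inclusive, epsilon), maps)
  lapply(keep, newCloneTree, inclusive = inclusive, valid = TRUE, epsilon = epsilon)
}

## depth of each node below the trunk
nodeDepths <- function(parent) {
  vapply(seq_along(parent), function(i) {
    d <- 0L; node <- i
    while (parent[node] != 0L) { d <- d + 1L; node <- parent[node] }
    d
  }, 0L)
}

#' Score candidate trees against cluster CCF posteriors and select one
#'
#' Each tree is scored by the joint posterior probability that a CCF
#' configuration drawn from the cluster posteriors (independently per
#' cluster and sample) satisfies the tree's lineage constraints exactly.
#' Common random draws are shared across candidates so scores are
#' comparable. The maximal-score tree is returned; ties are broken by fewer
#' total edges below the trunk (shallower tree), then by lexicographically
#' smaller parent map.
#'
#' @param trees non-empty list of [CloneTree-class] candidates.
#' @param clusters the [CloneClusters-class] providing posteriors; omit to
#'   rank by point-CCF violation only.
#' @param nDraws Monte-Carlo draws (default 1000).
#' @param seed integer seed.
#' @return The selected [CloneTree-class] with its `score` filled in.
#' @export
scoreAndSelectTree <- function(trees, clusters = NULL, nDraws = 1000L, seed = 1L) {
  if (!length(trees)) stop("no valid tree to select from")
  if (length(trees) == 1L && is.null(clusters)) return(trees[[1L]])
  k <- length(trees[[1L]]@parent)
  ns <- ncol(trees[[1L]]@inclusive)
  scores <- rep(NA_real_, length(trees))
  if (!is.null(clusters)) {
    set.seed(as.integer(seed))
    draws <- array(0, dim = c(nDraws, k, ns))
    for (j in seq_len(k))
      for (s in seq_len(ns)) {
        v <- clusters@clusterLogLik[j, s, ]
        p <- exp(v - logSumExp(v))
        draws[, j, s] <- clusters@grid[sample.int(length(p), nDraws, replace = TRUE, prob = p)]
      }
    for (ti in seq_along(trees)) {
      parent <- trees[[ti]]@parent
      ok <- rep(TRUE, nDraws)
      for (s in seq_len(ns)) {
        ccf <- draws[, , s, drop = FALSE]
        dim(ccf) <- c(nDraws, k)
        for (i in seq_len(k)) {
          pc <- if (parent[i] == 0L) 1 else ccf[, parent[i]]
          ok <- ok & (ccf[, i] <= pc + 1e-12)
        }
        for (p in seq_len(k)) {
          kids <- which(parent == p)
          if (length(kids))
            ok <- ok & (rowSums(ccf[, kids, drop = FALSE]) <= ccf[, p] + 1e-12)
        }
      }
      scores[ti] <- mean(ok)
    }
  } else {
    scores <- -vapply(trees, function(t) t@violation, 0)
  }
  best <- which(scores >= max(scores) - 1e-12)
  if (length(best) > 1L) {
    depths <- vapply(trees[best], function(t) sum(nodeDepths(t@parent)), 0L)
    best <- best[depths == min(depths)]
    if (length(best) > 1L) {
      keyOf <- vapply(trees[best], function(t) paste(t@parent, collapse = ","), "")
      best <- best[order(keyOf)[1L]]
    }
  }
  sel <- trees[[best[1L]]]
  sel@score <- scores[best[1L]]
  sel
}

#' Infer the clone tree from clusters
#'
#' Convenience wrapper: enumerate constraint-satisfying trees and select the
#' best by Monte-Carlo posterior score. When no tree satisfies the
#' constraints at `epsilon`, the least-violating tree over all rooted
#' topologies is returned with `valid = FALSE` so downstream analysis can
#' proceed with a diagnostic rather than fail on noisy data.
#'
#' @inheritParams enumerateValidTrees
#' @inheritParams scoreAndSelectTree
#' @return A [CloneTree-class].
#' @export
buildCloneTree <- function(clusters, epsilon = 0.10, nDraws = 1000L, seed = 1L) {
  cand <- enumerateValidTrees(clusters, epsilon)
  if (length(cand))
    return(scoreAndSelectTree(cand, clusters = if (methods::is(clusters, "CloneClusters")) clusters,
                              nDraws = nDraws, seed = seed))
  inclusive <- if (methods::is(clusters, "CloneClusters")) clusters@centers else clusters
  trunkCand <- which(apply(inclusive, 1L, function(x) all(x >= 1 - epsilon)))
  trunk <- if (length(trunkCand)) trunkCand[which.max(rowMeans(inclusive)[trunkCand])]
           else which.max(rowMeans(inclusive))
  maps <- allParentMaps(nrow(inclusive), trunk)
  all <- lapply(maps, newCloneTree, inclusive = inclusive, valid = FALSE, epsilon = epsilon)
  vio <- vapply(all, function(t) t@violation, 0)
  warning("no tree satisfies the lineage constraints at epsilon = ", epsilon,
          "; returning the least-violating tree (total violation ",
          signif(min(vio), 3), ")")
  sel <- scoreAndSelectTree(all[vio <= min(vio) + 1e-12],
                            clusters = if (methods::is(clusters, "CloneClusters")) clusters,
                            nDraws = nDraws, seed = seed)
  sel@valid <- FALSE
  sel
}

#' Build a clone tree from a known parent map
#'
#' For workflows where the topology is known (or fixed a priori): attaches
#' the per-sample inclusive CCFs to the given parent map and computes
#' exclusive fractions, recording whether the lineage constraints hold at
#' `epsilon`.
#'
#' @param parent integer parent map (0 = germline; exactly one trunk).
#' @param inclusive clusters x samples matrix of inclusive CCFs, or a
#'   [CloneClusters-class] whose centres are used.
#' @param epsilon constraint tolerance for the validity flag.
#' @return A [CloneTree-class].
#' @export
cloneTreeFromParent <- function(parent, inclusive, epsilon = 0.10) {
  if (methods::is(inclusive, "CloneClusters")) inclusive <- inclusive@centers
  tree <- newCloneTree(as.integer(parent), inclusive,
                       valid = treeSatisfies(as.integer(parent), inclusive, epsilon),
                       epsilon = epsilon)
  validObject(tree)
  tree
}

#' Exclusive clone fractions of a tree
#'
#' Exclusive fraction = inclusive CCF minus the sum of the children's
#' inclusive CCFs, per sample; negative values (possible under noise) are
#' clipped to zero and the total clipped magnitude is attached as attribute
#' `clipMagnitude`. Exclusive fractions telescope back to the trunk CCF.
#'
#' @param tree a [CloneTree-class].
#' @return clusters x samples matrix with attribute `clipMagnitude`.
#' @export
exclusiveFractions <- function(tree) {
  res <- exclusiveFromInclusive(tree@parent, tree@inclusive)
  if (res$clipMagnitude > 0)
    warning("negative exclusive fractions clipped (total ",
            signif(res$clipMagnitude, 3), ")")
  structure(res$fractions, clipMagnitude = res$clipMagnitude)
}

#' Newick string of a clone tree
#'
#' @param tree a [CloneTree-class].
#' @param labels node labels (default `C1..Ck` or the rownames of the
#'   inclusive matrix).
#' @return Newick string rooted at `germline`.
#' @export
cloneTreeNewick <- function(tree, labels = rownames(tree@inclusive) %||%
                              paste0("C", seq_along(tree@parent))) {
  build <- function(i) {
    kids <- which(tree@parent == i)
    lab <- if (i == 0L) "germline" else labels[i]
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")", lab)
  }
  trunk <- which(tree@parent == 0L)
  paste0("(", build(trunk), ")germline;")
}

#' Write a clone tree to JSON and Newick
#'
#' @param tree a [CloneTree-class].
#' @param path output path without extension; `<path>.json` and `<path>.nwk`
#'   are written.
#' @return Invisibly, the two paths.
#' @export
writeCloneTree <- function(tree, path) {
  labels <- rownames(tree@inclusive) %||% paste0("C", seq_along(tree@parent))
  obj <- list(nodes = labels,
              parent = ifelse(tree@parent == 0L, "germline", labels[tree@parent]),
              samples = colnames(tree@inclusive),
              inclusive_ccf = asplit(tree@inclusive, 1L),
              exclusive_fraction = asplit(tree@exclusive, 1L),
              constraints_satisfied = tree@valid,
              total_violation = tree@violation,
              score = tree@score)
  paths <- c(json = paste0(path, ".json"), newick = paste0(path, ".nwk"))
  jsonlite::write_json(obj, paths["json"], auto_unbox = TRUE, digits = NA)
  writeLines(cloneTreeNewick(tree, labels), paths["newick"])
  invisible(paths)
}
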