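#' @import methods
#' @importFrom stats dbinom rbinom rpois runif rnorm lm coef qt qbeta quantile
#'   median setNames predict var sd model.matrix aggregate optimise
#' @importFrom utils read.delim write.table
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Simulation configuration for a synthetic patient
#'
#' Describes a clone tree with per-clone constant exponential rates, initial
#' sizes at therapy start (day 0), the serial sampling design, and sequencing
#' parameters. Clones are numbered `1..nClones`; `parent[i]` gives the parent
#' clone of clone `i`, with `0` denoting the germline root (exactly one clone,
#' the trunk, has parent 0).
#'
#' @slot nClones number of clones.
#' @slot parent integer vector, parent clone per clone (0 = germline).
#' @slot initialSizes cells per clone at day 0 (exclusive counts, > 0).
#' @slot ratesPerDay per-clone exponential rate in 1/day (negative = decline).
#' @slot sampleDays strictly increasing integer days from therapy start.
#' @slot depth mean sequencing depth in reads.
#' @slot purity per-sample tumour purity in (0, 1].
#' @slot mutsPerClone somatic mutations private to each clone.
#' @slot bloodVolumeL total peripheral blood volume in litres (default 5).
#' @slot errorRate per-base sequencing error added to the expected allele
#'   fraction (default 0; see [simulateSequencing()]).
#' @slot seed integer seed driving all stochastic stages.
#'
#' @seealso [SimConfig()], [simulateClonalDynamics()]
#' @export
setClass("SimConfig", representation(
  nClones = "integer",
  parent = "integer",
  initialSizes = "numeric",
  ratesPerDay = "numeric",
  sampleDays = "numeric",
  depth = "numeric",
  purity = "numeric",
  mutsPerClone = "integer",
  bloodVolumeL = "numeric",
  errorRate = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  k <- object@nClones
  if (length(object@parent) != k) msg <- c(msg, "parent must have one entry per clone")
  if (sum(object@parent == 0L) != 1L) msg <- c(msg, "exactly one root clone (parent 0) required")
  if (any(object@parent < 0L) || any(object@parent > k))
    msg <- c(msg, "parent indices must be in 0..nClones")
  ## cycle check: every clone must reach the germline root
  for (i in seq_len(k)) {
    seen <- integer(); node <- i
    while (node != 0L) {
      if (node %in% seen) { msg <- c(msg, "parent map contains a cycle"); break }
      seen <- c(seen, node)
      node <- object@parent[node]
    }
    if (length(msg) && msg[length(msg)] == "parent map contains a cycle") break
  }
  if (any(object@initialSizes <= 0)) msg <- c(msg, "initialSizes must be positive")
  if (length(object@initialSizes) != k) msg <- c(msg, "initialSizes must have one entry per clone")
  if (length(object@ratesPerDay) != k) msg <- c(msg, "ratesPerDay must have one entry per clone")
  if (length(object@sampleDays) < 1L || any(diff(object@sampleDays) <= 0))
    msg <- c(msg, "sampleDays must be non-empty and strictly increasing")
  if (length(object@purity) != length(object@sampleDays))
    msg <- c(msg, "purity must have one entry per sample day")
  if (any(object@purity <= 0) || any(object@purity > 1))
    msg <- c(msg, "purity must lie in (0, 1]")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@bloodVolumeL <= 0) msg <- c(msg, "bloodVolumeL must be positive")
  if (object@errorRate < 0 || object@errorRate >= 1) msg <- c(msg, "errorRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nClones number of clones.
#' @param parent integer parent map (0 = germline root); default a star tree
#'   with clone 1 as trunk.
#' @param initialSizes cells per clone at day 0.
#' @param ratesPerDay exponential rates in 1/day. The defaults emulate a
#'   treatment-resistant relapse: a large declining trunk (-0.002/day) and
#'   small resistant subclones growing at 0.015-0.019/day.
#' @param sampleDays days from therapy start at which blood is drawn.
#' @param depth mean sequencing depth (reads).
#' @param purity tumour purity per sample (recycled if scalar).
#' @param mutsPerClone mutations private to each clone.
#' @param bloodVolumeL peripheral blood volume in litres.
#' @param errorRate per-base sequencing error rate (default 0).
#' @param seed integer seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(nClones = 3, initialSizes = c(1e11, 3e6, 27e3),
#'                  ratesPerDay = c(-0.002, 0.015, 0.019))
#' @export
SimConfig <- function(nClones = 3L,
                      parent = c(0L, rep(1L, nClones - 1L)),
                      initialSizes = c(1e11, 3e6, 2.7e4)[seq_len(nClones)],
                      ratesPerDay = c(-0.002, 0.015, 0.019)[seq_len(nClones)],
                      sampleDays = c(0, 365, 730, 985),
                      depth = 1000,
                      purity = 0.9,
                      mutsPerClone = 5L,
                      bloodVolumeL = 5,
                      errorRate = 0,
                      seed = 1L) {
  if (length(purity) == 1L) purity <- rep(purity, length(sampleDays))
  new("SimConfig",
      nClones = as.integer(nClones), parent = as.integer(parent),
      initialSizes = as.numeric(initialSizes), ratesPerDay = as.numeric(ratesPerDay),
      sampleDays = as.numeric(sampleDays), depth = as.numeric(depth),
      purity = as.numeric(purity), mutsPerClone = as.integer(mutsPerClone),
      bloodVolumeL = as.numeric(bloodVolumeL), errorRate = as.numeric(errorRate),
      seed = as.integer(seed))
}

#' Synthetic patient with known ground truth
#'
#' Holds the deterministic clonal trajectories implied by a [SimConfig-class]:
#' exclusive per-clone cell counts at each sampled day, the absolute
#' lymphocyte count (ALC) they imply, inclusive cancer cell fractions (CCFs),
#' and the simulated mutation catalogue. Exclusive counts are primary;
#' inclusive CCFs are derived by summing a clone with its descendants.
#'
#' @slot config the generating [SimConfig-class].
#' @slot cellCounts clones x days matrix of exclusive cell counts.
#' @slot alcPerUl ALC per microlitre at each sampled day.
#' @slot inclusiveCCF clones x days matrix of inclusive CCFs.
#' @slot mutations `DataFrame` of simulated mutations (one row each) with
#'   clone membership and genomic coordinates.
#' @slot sampleMeta `DataFrame` of per-sample metadata (sample, patient, day,
#'   purity, alc_per_ul).
#' @export
setClass("CloneSim", representation(
  config = "SimConfig",
  cellCounts = "matrix",
  alcPerUl = "numeric",
  inclusiveCCF = "matrix",
  mutations = "DataFrame",
  sampleMeta = "DataFrame"
))

#' @export
setMethod("show", "CloneSim", function(object) {
  cat("CloneSim:", object@config@nClones, "clones,",
      length(object@config@sampleDays), "samples (days",
      paste(object@config@sampleDays, collapse = ", "), ")\n")
  cat("  ALC per ul:", signif(object@alcPerUl, 4), "\n")
  cat("  mutations:", nrow(object@mutations), "\n")
})

#' Discretised posterior over cancer cell fraction
#'
#' Posterior mass for the CCF of one mutation (or clone) in one sample on a
#' uniform grid over \[0, 1\].
#'
#' @slot grid CCF grid values in \[0, 1\].
#' @slot probs probability mass per grid point (sums to 1).
#' @seealso [afToCCFPosterior()], [ccfPointEstimate()]
#' @export
setClass("CCFPosterior", representation(grid = "numeric", probs = "numeric"))

setValidity("CCFPosterior", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@probs))
    msg <- c(msg, "grid and probs must have equal length")
  if (any(object@grid < 0) || any(object@grid > 1))
    msg <- c(msg, "grid must lie within [0, 1]")
  if (abs(sum(object@probs) - 1) > 1e-9)
    msg <- c(msg, "probs must sum to 1 (tolerance 1e-9)")
  if (any(object@probs < 0)) msg <- c(msg, "probs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CCFPosterior", function(object) {
  cat(sprintf("CCFPosterior on %d-point grid: mode %.3f, mean %.3f\n",
              length(object@grid), ccfPointEstimate(object, "mode"),
              ccfPointEstimate(object, "mean")))
})

#' Mutation clusters across serial samples
#'
#' Result of fitting a finite mixture to per-mutation multi-sample CCF
#' likelihoods by EM, with the number of components chosen by BIC.
#'
#' @slot assignment integer cluster id per mutation (named by mutation key).
#' @slot responsibility mutations x clusters matrix of posterior membership.
#' @slot centers clusters x samples matrix of point CCFs (mode of the cluster
#'   posterior).
#' @slot clusterLogLik clusters x samples x grid array: summed member
#'   log-likelihoods defining each cluster's CCF posterior.
#' @slot grid CCF grid.
#' @slot logLik fitted mixture log-likelihood.
#' @slot bic BIC per candidate k (named numeric).
#' @slot k selected number of clusters.
#' @export
setClass("CloneClusters", representation(
  assignment = "integer",
  responsibility = "matrix",
  centers = "matrix",
  clusterLogLik = "array",
  grid = "numeric",
  logLik = "numeric",
  bic = "numeric",
  k = "integer"
))

#' @export
setMethod("show", "CloneClusters", function(object) {
  cat("CloneClusters: k =", object@k, "over", nrow(object@responsibility),
      "mutations,", ncol(object@centers), "samples\n")
  cat("  sizes:", paste(tabulate(object@assignment, object@k), collapse = ", "), "\n")
  print(round(object@centers, 3))
})

#' Rooted clone tree with per-sample CCFs
#'
#' Nodes are mutation clusters plus an implicit germline root (parent id 0).
#' For every sample the inclusive CCF of a parent must cover each child and
#' the sum of its children (pigeonhole constraint), up to a tolerance.
#' Exclusive fractions are inclusive CCFs minus the children's inclusive
#' CCFs, floored at zero.
#'
#' @slot parent integer parent map over clusters (0 = germline).
#' @slot inclusive clusters x samples matrix of inclusive CCFs.
#' @slot exclusive clusters x samples matrix of exclusive fractions.
#' @slot score Monte-Carlo posterior constraint mass (NA if unscored).
#' @slot valid TRUE when the point CCFs satisfy the constraints at the
#'   tolerance used for enumeration.
#' @slot violation total constraint violation of the point CCFs (0 if valid).
#' @slot clipMagnitude total negative mass clipped when computing exclusive
#'   fractions.
#' @export
setClass("CloneTree", representation(
  parent = "integer",
  inclusive = "matrix",
  exclusive = "matrix",
  score = "numeric",
  valid = "logical",
  violation = "numeric",
  clipMagnitude = "numeric"
))

setValidity("CloneTree", function(object) {
  msg <- character()
  k <- length(object@parent)
  if (sum(object@parent == 0L) != 1L) msg <- c(msg, "exactly one trunk (parent 0) required")
  for (i in seq_len(k)) {
    seen <- integer(); node <- i
    while (node != 0L) {
      if (node %in% seen) { msg <- c(msg, "cycle in parent map"); break }
      seen <- c(seen, node); node <- object@parent[node]
    }
  }
  if (nrow(object@inclusive) != k) msg <- c(msg, "inclusive must have one row per cluster")
  if (length(msg)) unique(msg) else TRUE
})

#' @export
setMethod("show", "CloneTree", function(object) {
  cat("CloneTree over", length(object@parent), "clusters",
      if (isTRUE(object@valid)) "(constraints satisfied)" else
        sprintf("(LEAST-VIOLATING, total violation %.3g)", object@violation), "\n")
  cat("  parent map:", paste(object@parent, collapse = " "), "\n")
  if (!is.na(object@score)) cat("  posterior constraint mass:", signif(object@score, 3), "\n")
  cat("  newick:", cloneTreeNewick(object), "\n")
})

#' Fitted exponential growth/decline of one clone
#'
#' @slot clone clone/cluster identifier.
#' @slot rate exponential rate g in 1/day.
#' @slot rateUncertainty s.d. (two-point Monte-Carlo) or s.e. (regression) of g.
#' @slot uncertaintyType `"sd"` or `"se"`.
#' @slot rateCI 95% interval for g (posterior percentile when Monte-Carlo
#'   draws are available, else t-interval from the regression).
#' @slot intercept fitted log cell count at day 0.
#' @slot n0 back-extrapolated cells at therapy start (day 0).
#' @slot n0CI 95% interval for n0.
#' @slot nPoints number of detected observations used.
#' @slot method one of `"two_point"`, `"regression"`, `"alc_fit"`, `"shared"`.
#' @slot rateIsLowerBound TRUE when the earliest point entering the fit was an
#'   upper bound on the clone size, so the reported rate is a lower bound.
#' @export
setClass("GrowthFit", representation(
  clone = "character",
  rate = "numeric",
  rateUncertainty = "numeric",
  uncertaintyType = "character",
  rateCI = "numeric",
  intercept = "numeric",
  n0 = "numeric",
  n0CI = "numeric",
  nPoints = "integer",
  method = "character",
  rateIsLowerBound = "logical"
))

setValidity("GrowthFit", function(object) {
  msg <- character()
  if (length(object@rateCI) != 2L || length(object@n0CI) != 2L)
    msg <- c(msg, "rateCI and n0CI must have length 2")
  if (!is.na(object@n0) && !any(is.na(object@n0CI)) &&
      (object@n0 < object@n0CI[1] - 1e-9 || object@n0 > object@n0CI[2] + 1e-9))
    msg <- c(msg, "n0CI must cover the n0 point estimate")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit [%s] clone %s: g = %s%.4f/day (%s %.4f), n = %d\n",
              object@method, object@clone,
              if (isTRUE(object@rateIsLowerBound)) ">" else "",
              object@rate, object@uncertaintyType, object@rateUncertainty,
              object@nPoints))
  if (!is.na(object@n0))
    cat(sprintf("  N0 at day 0: %.3g cells (95%% CI %.3g-%.3g)\n",
                object@n0, object@n0CI[1], object@n0CI[2]))
})

#' Per-patient analysis report
#'
#' Container returned by [runPipeline()]: every stage's output plus
#' provenance.
#'
#' @slot ccf `SummarizedExperiment` from [computeCCF()] with per-mutation
#'   CCF posteriors.
#' @slot clusters [CloneClusters-class].
#' @slot tree [CloneTree-class] (may be absent for single-sample patients).
#' @slot trajectories `DataFrame` of per-clone per-day absolute cell counts.
#' @slot fits `DataFrame` of per-clone growth fits.
#' @slot alcFit list with predicted ALC series and log-domain RMSE.
#' @slot status character: `"complete"` or a notice (e.g. kinetics skipped).
#' @slot provenance list with config, seed, config hash and package version.
#' @export
setClass("PatientReport", representation(
  ccf = "ANY",
  clusters = "ANY",
  tree = "ANY",
  trajectories = "ANY",
  fits = "ANY",
  alcFit = "ANY",
  status = "character",
  provenance = "list"
))

#' @export
setMethod("show", "PatientReport", function(object) {
  cat("PatientReport (", object@status, ")\n", sep = "")
  if (!is.null(object@clusters)) cat("  clusters: k =", object@clusters@k, "\n")
  if (!is.null(object@fits) && nrow(object@fits))
    cat("  fitted clones:", paste(object@fits$clone, collapse = ", "), "\n")
  if (!is.null(object@alcFit)) cat("  ALC log-RMSE:", signif(object@alcFit$rmseLog, 3), "\n")
})
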