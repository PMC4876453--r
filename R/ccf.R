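## cancer cell fraction inference from allele counts

defaultGrid <- function(step = 0.01) seq(0, 1, by = step)

## log-likelihood of (alt | depth) across a CCF grid
ccfLogLik <- function(alt, depth, purity, totalCn, multiplicity, grid) {
  af <- expectedAlleleFraction(grid, purity, totalCn, multiplicity)
  ## keep the likelihood finite at the grid boundaries (af exactly 0 or 1)
  af <- pmin(pmax(af, 1e-12), 1 - 1e-12)
  dbinom(alt, depth, af, log = TRUE)
}

## mutant multiplicity implied by the observed allele fraction under the
## clonal assumption: m = round(af * (purity q + 2 (1 - purity)) / purity),
## clamped to 1..q. Maximising the binomial likelihood over m directly is
## degenerate (m = q with a smaller CCF always fits at least as well), so
## the nearest-integer convention is used.
autoMultiplicity <- function(alt, depth, purity, totalCn) {
  af <- alt / depth
  m <- round(af * (purity * totalCn + 2 * (1 - purity)) / purity)
  max(1L, min(as.integer(totalCn), as.integer(m)))
}

#' Convert allele counts to a CCF posterior
#'
#' For each grid value `c`, the likelihood is
#' `Binomial(alt | alt + ref, af(c))` with
#' `af(c) = purity * m * c / (purity * q + (1 - purity) * 2)` clipped to
#' \[0, 1\]; a uniform prior over the grid is applied and the mass
#' normalised. `q` is the local total copy number and `m` the mutant
#' multiplicity.
#'
#' @param alt,ref alt and ref read counts (alt + ref > 0).
#' @param purity tumour purity in (0, 1].
#' @param totalCn local total copy number `q` (>= 1).
#' @param multiplicity mutant multiplicity `m` (1 <= m <= q), or `"auto"`
#'   for the nearest integer implied by the observed allele fraction under
#'   the clonal assumption, clamped to 1..q.
#' @param gridStep grid spacing (default 0.01).
#' @return A [CCFPosterior-class].
#' @examples
#' ## clonal heterozygous mutation in a pure sample: af = 0.5 -> CCF 1
#' p <- afToCCFPosterior(50, 50, purity = 1)
#' ccfPointEstimate(p, "mode")
#' @export
afToCCFPosterior <- function(alt, ref, purity, totalCn = 2, multiplicity = 1,
                             gridStep = 0.01) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  if (alt < 0 || ref < 0 || alt + ref == 0) stop("need alt + ref > 0 with non-negative counts")
  if (totalCn < 1) stop("totalCn must be >= 1")
  grid <- defaultGrid(gridStep)
  if (identical(multiplicity, "auto"))
    multiplicity <- autoMultiplicity(alt, alt + ref, purity, totalCn)
  if (multiplicity < 1 || multiplicity > totalCn)
    stop("multiplicity must satisfy 1 <= m <= totalCn")
  if (expectedAlleleFraction(1, purity, totalCn, multiplicity) <= 0)
    stop("model degenerate: af(CCF = 1) is 0")
  ll <- ccfLogLik(alt, alt + ref, purity, totalCn, multiplicity, grid)
  probs <- exp(ll - logSumExp(ll))
  new("CCFPosterior", grid = grid, probs = probs / sum(probs))
}

#' Summarise a CCF posterior
#'
#' @param post a [CCFPosterior-class].
#' @param kind `"mode"` (ties broken toward the larger CCF) or `"mean"`.
#' @return A single CCF value.
#' @export
ccfPointEstimate <- function(post, kind = c("mode", "mean")) {
  kind <- match.arg(kind)
  if (kind == "mean") return(sum(post@grid * post@probs))
  mx <- max(post@probs)
  post@grid[max(which(post@probs >= mx - 1e-12))]
}

#' Central credible interval of a CCF posterior
#'
#' @param post a [CCFPosterior-class].
#' @param level interval mass (default 0.95).
#' @return length-2 numeric (lower, upper) on the grid.
#' @export
ccfCredibleInterval <- function(post, level = 0.95) {
  cum <- cumsum(post@probs)
  a <- (1 - level) / 2
  c(post@grid[which(cum >= a)[1]], post@grid[which(cum >= 1 - a)[1]])
}

#' Compute CCF posteriors for a mutation table
#'
#' Vectorised front end to [afToCCFPosterior()]: takes long-format mutation
#' observations over one patient's serial samples and returns a
#' `SummarizedExperiment` (mutations x samples) whose assays hold the read
#' counts and point CCFs, with the full grid of per-mutation per-sample
#' log-likelihoods in `metadata()` for downstream clustering.
#'
#' Mutations absent from a sample are treated as alt = 0 at that sample's
#' median observed depth (so undetected mutations contribute evidence of a
#' low CCF rather than missing data).
#'
#' @param mutations `data.frame` with columns chrom, pos, ref, alt (alleles),
#'   sample, t_alt_count, t_ref_count, and optionally gene, total_cn,
#'   minor_cn, multiplicity. A `mutation` key column is synthesised from
#'   chrom:pos:ref>alt when missing.
#' @param samples `data.frame` with columns sample, day, purity (and
#'   optionally patient, alc_per_ul); defines the sample (column) order.
#' @param gridStep grid spacing.
#' @param multiplicity fixed multiplicity or `"auto"` (per observation).
#' @return A `SummarizedExperiment` with assays `alt`, `ref`, `ccfMode`,
#'   `ccfMean`; `metadata()$logLik` is a mutations x samples x grid array and
#'   `metadata()$grid` the CCF grid.
#' @export
computeCCF <- function(mutations, samples, gridStep = 0.001, multiplicity = 1) {
  mutations <- as.data.frame(mutations)
  samples <- as.data.frame(samples)
  need <- c("chrom", "pos", "sample", "t_alt_count", "t_ref_count")
  miss <- setdiff(need, names(mutations))
  if (length(miss)) stop("mutations table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(c("sample", "day", "purity") %in% names(samples)))
    stop("samples table needs columns sample, day, purity")
  refCol <- if ("ref" %in% names(mutations)) "ref" else "ref_allele"
  altCol <- if ("alt" %in% names(mutations)) "alt" else "alt_allele"
  if (!"mutation" %in% names(mutations))
    mutations$mutation <- sprintf("%s:%d:%s>%s", mutations$chrom, mutations$pos,
                                  mutations[[refCol]], mutations[[altCol]])
  if (!"total_cn" %in% names(mutations)) mutations$total_cn <- 2L
  keys <- unique(mutations$mutation)
  sids <- samples$sample
  grid <- defaultGrid(gridStep)
  nm <- length(keys); ns <- length(sids); ng <- length(grid)
  ll <- array(0, dim = c(nm, ns, ng), dimnames = list(keys, sids, NULL))
  altM <- refM <- matrix(NA_real_, nm, ns, dimnames = list(keys, sids))
  qM <- matrix(2, nm, ns, dimnames = list(keys, sids))
  mM <- matrix(if (identical(multiplicity, "auto")) 1 else multiplicity,
               nm, ns, dimnames = list(keys, sids))
  medDepth <- vapply(sids, function(s) {
    d <- mutations$t_alt_count[mutations$sample == s] +
         mutations$t_ref_count[mutations$sample == s]
    if (length(d)) median(d) else 100
  }, 0)
  for (s in seq_len(ns)) {
    sub <- mutations[mutations$sample == sids[s], ]
    idx <- match(sub$mutation, keys)
    altM[idx, s] <- sub$t_alt_count
    refM[idx, s] <- sub$t_ref_count
    missing <- which(is.na(altM[, s]))
    if (length(missing)) {
      altM[missing, s] <- 0
      refM[missing, s] <- round(medDepth[s])
    }
    qM[idx, s] <- sub$total_cn
    for (i in seq_len(nm)) {
      m <- multiplicity
      if (identical(m, "auto")) {
        m <- autoMultiplicity(altM[i, s], altM[i, s] + refM[i, s],
                              samples$purity[s], qM[i, s])
        mM[i, s] <- m
        ll[i, s, ] <- ccfLogLik(altM[i, s], altM[i, s] + refM[i, s],
                                samples$purity[s], qM[i, s], m, grid)
      } else {
        ll[i, s, ] <- ccfLogLik(altM[i, s], altM[i, s] + refM[i, s],
                                samples$purity[s], qM[i, s], m, grid)
      }
    }
  }
  post <- exp(ll - array(apply(ll, c(1, 2), logSumExp), dim = dim(ll)))
  gridArr <- array(rep(grid, each = nm * ns), dim = dim(ll))
  ccfMean <- apply(post * gridArr, c(1, 2), sum)
  ccfMode <- apply(ll, c(1, 2), function(x) grid[max(which(x >= max(x) - 1e-12))])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(alt = altM, ref = refM, ccfMode = ccfMode, ccfMean = ccfMean,
                  totalCn = qM, multiplicity = mM),
    colData = S4Vectors::DataFrame(samples, row.names = sids))
  S4Vectors::metadata(se)$logLik <- ll
  S4Vectors::metadata(se)$grid <- grid
  se
}
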