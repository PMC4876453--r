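## synthetic patient generator: deterministic clonal dynamics + stochastic
## sequencing and assay layers

## all descendants (not including the clone itself) under a parent map
descendantsOf <- function(parent, clone) {
  k <- length(parent)
  out <- integer()
  frontier <- clone
  while (length(frontier)) {
    kids <- which(parent %in% frontier)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Simulate deterministic clonal dynamics
#'
#' Propagates every clone forward from day 0 under constant exponential
#' rates, `N_c(t) = N_c(0) exp(g_c t)`, evaluates the absolute lymphocyte
#' count implied by the total circulating burden
#' (`ALC(t) = sum_c N_c(t) / (V x 10^6 ul/l)`), computes inclusive CCFs
#' (a clone plus all its descendants over the total), and lays down
#' `mutsPerClone` private mutations per clone whose true CCF equals their
#' clone's inclusive CCF.
#'
#' The trajectories are fully deterministic; randomness enters only in
#' [simulateSequencing()] and [simulateAssayData()].
#'
#' @param config a [SimConfig-class].
#' @return A [CloneSim-class] truth set.
#' @examples
#' sim <- simulateClonalDynamics(SimConfig())
#' sim
#' @export
simulateClonalDynamics <- function(config) {
  validObject(config)
  k <- config@nClones
  days <- config@sampleDays
  cells <- outer(seq_len(k), days,
                 function(i, t) config@initialSizes[i] * exp(config@ratesPerDay[i] * t))
  dimnames(cells) <- list(paste0("clone", seq_len(k)), paste0("d", days))
  total <- colSums(cells)
  alc <- total / (config@bloodVolumeL * 1e6)
  incl <- cells
  for (i in seq_len(k)) {
    idx <- c(i, descendantsOf(config@parent, i))
    incl[i, ] <- colSums(cells[idx, , drop = FALSE]) / total
  }
  nm <- k * config@mutsPerClone
  clone <- rep(seq_len(k), each = config@mutsPerClone)
  muts <- S4Vectors::DataFrame(
    mutation = sprintf("mut_c%d_%d", clone, sequence(rep(config@mutsPerClone, k))),
    clone = clone,
    chrom = as.character(((seq_len(nm) - 1L) %% 22L) + 1L),
    pos = seq_len(nm) * 1000000L,
    ref = rep(c("A", "C", "G", "T"), length.out = nm),
    alt = rep(c("G", "T", "A", "C"), length.out = nm),
    gene = sprintf("GENE%02d", seq_len(nm)))
  sampleMeta <- S4Vectors::DataFrame(
    sample = sprintf("S%02d", seq_along(days)),
    patient = "SIM01",
    day = days,
    purity = config@purity,
    alc_per_ul = alc)
  new("CloneSim", config = config, cellCounts = cells, alcPerUl = unname(alc),
      inclusiveCCF = incl, mutations = muts, sampleMeta = sampleMeta)
}

#' Simulate read counts for every mutation in every sample
#'
#' For a mutation with true CCF `c` in a sample of purity `p`, local total
#' copy number `q` and mutant multiplicity `m`, the expected allele fraction
#' is `af = p m c / (p q + (1 - p) 2)`. Per mutation and sample the realised
#' depth is Poisson around the mean depth (floored at 1 read) and the alt
#' count is Binomial(depth, af). An optional per-base error rate is added to
#' the expected allele fraction (`af + errorRate (1 - af)`), so a CCF-0
#' mutation can still draw alt reads when `errorRate > 0`.
#'
#' @param sim a [CloneSim-class] from [simulateClonalDynamics()].
#' @param depth mean depth; defaults to the config value.
#' @param purity per-sample purity; defaults to the config value.
#' @param seed integer seed; defaults to the config seed.
#' @param errorRate per-base error; defaults to the config value (0).
#' @param totalCn,multiplicity local copy state used for every mutation
#'   (defaults 2 and 1: diploid heterozygous).
#' @return A `data.frame` of mutation observations, one row per mutation per
#'   sample, with columns patient, sample, day, chrom, pos, ref, alt, gene,
#'   mutation, clone, t_alt_count, t_ref_count, total_cn, minor_cn,
#'   multiplicity, true_ccf.
#' @export
simulateSequencing <- function(sim, depth = sim@config@depth,
                               purity = sim@config@purity,
                               seed = sim@config@seed,
                               errorRate = sim@config@errorRate,
                               totalCn = 2L, multiplicity = 1L) {
  if (depth <= 0) stop("depth must be positive")
  days <- sim@config@sampleDays
  if (length(purity) == 1L) purity <- rep(purity, length(days))
  muts <- as.data.frame(sim@mutations)
  nm <- nrow(muts); ns <- length(days)
  set.seed(as.integer(seed))
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    ccf <- sim@inclusiveCCF[muts$clone, s]
    af <- expectedAlleleFraction(ccf, purity[s], totalCn, multiplicity)
    af <- af + errorRate * (1 - af)
    dp <- pmax(1L, rpois(nm, depth))
    alt <- rbinom(nm, dp, pmin(1, af))
    out[[s]] <- data.frame(
      patient = "SIM01", sample = sprintf("S%02d", s), day = days[s],
      muts[, c("chrom", "pos", "ref", "alt", "gene", "mutation", "clone")],
      t_alt_count = alt, t_ref_count = dp - alt,
      total_cn = totalCn, minor_cn = ifelse(totalCn >= 2L, 1L, 0L),
      multiplicity = multiplicity, true_ccf = ccf,
      row.names = NULL, check.names = FALSE)
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "alt"] <- "alt_allele"
  names(res)[names(res) == "ref"] <- "ref_allele"
  res
}

## expected allele fraction under the purity/copy-number model
expectedAlleleFraction <- function(ccf, purity, totalCn, multiplicity) {
  pmin(1, pmax(0, purity * multiplicity * ccf /
                    (purity * totalCn + (1 - purity) * 2)))
}

#' Simulate droplet and single-cell assay data
#'
#' Emulates the inputs of the two validation assays at one sampled day:
#' a rare-cell droplet screen in which each screened cell is positive with
#' probability equal to the clone's true prevalence (inclusive CCF scaled by
#' `tumourFraction`), and a single-cell allele-specific expression panel in
#' which mutant cells express the mutant allele and normal cells show only a
#' linear background proportional to their normal-allele signal.
#'
#' @param sim a [CloneSim-class].
#' @param clone clone index whose marker mutation is assayed.
#' @param sampleIndex index into the sampled days (default last sample).
#' @param nCellsScreened droplets/cells screened in the rare-cell assay.
#' @param nSingleCells cells on the single-cell panel.
#' @param mutantSignalMean,signalSd mutant-allele signal level in mutant
#'   cells and Gaussian signal noise.
#' @param backgroundSlope background mutant signal per unit normal signal in
#'   true-normal cells.
#' @param tumourFraction fraction of screened cells that are tumour (1 =
#'   screen of the circulating CLL compartment).
#' @param prevalence override the mutant-cell prevalence directly (bypasses
#'   the clone's CCF); useful for spike-in style designs.
#' @param seed integer seed.
#' @return list with `droplets` (a one-row `data.frame`: n_droplets,
#'   n_positive, cells_screened, prevalence_true) and `cells` (a `data.frame`
#'   with cell, truth, mutant_level, normal_level).
#' @export
simulateAssayData <- function(sim, clone = sim@config@nClones,
                              sampleIndex = length(sim@config@sampleDays),
                              nCellsScreened = 1e6, nSingleCells = 200L,
                              mutantSignalMean = 1, signalSd = 0.05,
                              backgroundSlope = 0.05, tumourFraction = 1,
                              prevalence = NULL, seed = sim@config@seed) {
  if (nCellsScreened <= 0) stop("nCellsScreened must be positive")
  prev <- prevalence %||% (sim@inclusiveCCF[clone, sampleIndex] * tumourFraction)
  set.seed(as.integer(seed))
  npos <- rbinom(1L, as.integer(nCellsScreened), prev)
  droplets <- data.frame(n_droplets = as.integer(nCellsScreened),
                         n_positive = npos,
                         cells_screened = as.integer(nCellsScreened),
                         prevalence_true = prev)
  isMut <- runif(nSingleCells) < prev
  normal <- pmax(0, rnorm(nSingleCells, 1, signalSd))
  mutant <- ifelse(isMut,
                   pmax(0, rnorm(nSingleCells, mutantSignalMean, signalSd)),
                   pmax(0, backgroundSlope * normal + rnorm(nSingleCells, 0, signalSd / 5)))
  cells <- data.frame(cell = sprintf("cell%04d", seq_len(nSingleCells)),
                      truth = ifelse(isMut, "mutant", "normal"),
                      mutant_level = mutant, normal_level = normal)
  list(droplets = droplets, cells = cells)
}

#' Write a simulated patient to disk
#'
#' Emits the standard input tables consumed by the pipeline: `mutations.tsv`
#' (one row per mutation per sample with read counts), `samples.tsv`,
#' `segments.tsv` (diploid genome, 1-based inclusive ends), and
#' `truth.json` with the generating parameters and trajectories.
#'
#' @param sim a [CloneSim-class].
#' @param dir output directory (created if needed).
#' @param ... passed to [simulateSequencing()].
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSimulation <- function(sim, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- simulateSequencing(sim, ...)
  mut <- obs[, c("patient", "sample", "chrom", "pos", "ref_allele", "alt_allele",
                 "gene", "t_alt_count", "t_ref_count")]
  names(mut)[names(mut) == "ref_allele"] <- "ref"
  names(mut)[names(mut) == "alt_allele"] <- "alt"
  samples <- as.data.frame(sim@sampleMeta)
  segs <- do.call(rbind, lapply(samples$sample, function(s)
    data.frame(sample = s, chrom = as.character(1:22), start = 1L,
               end = 250000000L, total_cn = 2L, minor_cn = 1L)))
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             samples = file.path(dir, "samples.tsv"),
             segments = file.path(dir, "segments.tsv"),
             truth = file.path(dir, "truth.json"))
  write.table(mut, paths["mutations"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(samples, paths["samples"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(segs, paths["segments"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim@config
  truth <- list(
    parent = cfg@parent, initial_sizes = cfg@initialSizes,
    rates_per_day = cfg@ratesPerDay, sample_days = cfg@sampleDays,
    blood_volume_l = cfg@bloodVolumeL, seed = cfg@seed,
    cell_counts = asplit(sim@cellCounts, 1L),
    alc_per_ul = sim@alcPerUl,
    inclusive_ccf = asplit(sim@inclusiveCCF, 1L),
    mutation_clone = setNames(as.list(sim@mutations$clone), sim@mutations$mutation))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
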