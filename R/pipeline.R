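## end-to-end orchestration: tables in, per-patient report out

#' Run the full clonal-kinetics pipeline
#'
#' Reads the mutation, segment and sample tables, computes per-mutation CCF
#' posteriors, clusters mutations into subclones, infers the clone tree
#' under lineage constraints, converts clone fractions to absolute
#' circulating cell counts, fits per-clone exponential kinetics with
#' posterior-propagated intervals, back-extrapolates clone sizes to therapy
#' initiation and assesses the ALC fit. All randomness flows from the
#' single configuration seed, so a rerun with the same configuration
#' reproduces the report exactly.
#'
#' Patients with a single sample get CCF and clustering output only;
#' kinetics are skipped with a notice in `status`.
#'
#' @param config named list as returned by [readPipelineConfig()], or a
#'   path to a configuration file. Required entries: `mutations`,
#'   `segments`, `samples` (paths) and `seed`; optional: `blood_volume_l`
#'   (5), `grid_step` (0.001), `k_max` (6), `epsilon` (0.10),
#'   `detection_ccf` (0.01), `upper_bound_fraction` (0.01), `mc_draws`
#'   (1000), `ccf_mode` ("exclusive").
#' @param outDir optional directory; when given, the report tables
#'   (ccf.tsv, clusters.tsv, kinetics.tsv, trajectories.tsv, tree.json,
#'   tree.nwk) are written there.
#' @return A [PatientReport-class].
#' @export
runPipeline <- function(config, outDir = NULL) {
  configHash <- NA_character_
  if (is.character(config) && length(config) == 1L) {
    configHash <- unname(tools::md5sum(config))
    config <- readPipelineConfig(config)
  }
  for (k in c("mutations", "segments", "samples", "seed"))
    if (is.null(config[[k]])) stop("configuration lacks '", k, "'")
  seed <- as.integer(config$seed)
  muts <- readVariants(config$mutations)
  if (!nrow(muts)) stop(config$mutations, ": empty mutation table")
  segs <- readSegments(config$segments)
  samples <- readSamples(config$samples)
  muts <- annotateCopyNumber(muts, segs)
  ccf <- computeCCF(muts, samples, gridStep = config$grid_step %||% 0.001)
  clusters <- clusterCCF(ccf, kMax = config$k_max %||% 6, seed = seed)
  clTab <- data.frame(mutation = names(clusters@assignment),
                      cluster = paste0("C", clusters@assignment),
                      responsibility = clusters@responsibility[
                        cbind(seq_along(clusters@assignment), clusters@assignment)])
  prov <- list(config = config, seed = seed, configHash = configHash,
               package = as.character(utils::packageVersion("clonekin")))
  if (nrow(samples) < 2L) {
    report <- new("PatientReport", ccf = ccf, clusters = clusters, tree = NULL,
                  trajectories = NULL, fits = NULL, alcFit = NULL,
                  status = "single_sample: kinetics skipped", provenance = prov)
  } else {
    tree <- buildCloneTree(clusters, epsilon = config$epsilon %||% 0.10,
                           nDraws = as.integer(config$mc_draws %||% 1000), seed = seed)
    kin <- cloneGrowthFits(tree, samples, clusters,
                           mode = config$ccf_mode %||% "exclusive",
                           detectionCCF = config$detection_ccf %||% 0.01,
                           upperBoundFraction = config$upper_bound_fraction %||% 0.01,
                           bloodVolumeL = config$blood_volume_l %||% 5,
                           mcDraws = as.integer(config$mc_draws %||% 1000),
                           seed = seed)
    alcFit <- if (length(kin$fits))
      predictALC(kin$fits, samples$day, config$blood_volume_l %||% 5,
                 observedAlc = samples$alc_per_ul)
    report <- new("PatientReport", ccf = ccf, clusters = clusters, tree = tree,
                  trajectories = kin$trajectories, fits = kin$table,
                  alcFit = alcFit, status = "complete", provenance = prov)
  }
  if (!is.null(outDir)) writePatientReport(report, clTab, outDir)
  report
}

writePatientReport <- function(report, clTab, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  se <- report@ccf
  ccfTab <- data.frame(
    mutation = rep(rownames(SummarizedExperiment::assay(se, "ccfMode")),
                   ncol(se)),
    sample = rep(colnames(se), each = nrow(se)),
    ccf_mode = as.vector(SummarizedExperiment::assay(se, "ccfMode")),
    ccf_mean = as.vector(SummarizedExperiment::assay(se, "ccfMean")))
  writeReportTable(ccfTab, file.path(outDir, "ccf.tsv"))
  writeReportTable(clTab, file.path(outDir, "clusters.tsv"))
  if (!is.null(report@tree)) {
    writeCloneTree(report@tree, file.path(outDir, "tree"))
    writeReportTable(report@fits, file.path(outDir, "kinetics.tsv"))
    writeReportTable(report@trajectories, file.path(outDir, "trajectories.tsv"))
  }
  prov <- report@provenance
  prov$config <- NULL
  jsonlite::write_json(c(prov, list(status = report@status)),
                       file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
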