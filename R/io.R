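## readers and writers for the standard input tables
## coordinates are 1-based inclusive throughout (MAF/VCF convention)

#' Read a somatic mutation table
#'
#' TSV input must carry 1-based positions and alt/ref read counts (columns
#' chrom, pos, ref, alt, t_alt_count, t_ref_count, plus sample and optional
#' patient/gene). VCF input is parsed with VariantAnnotation; per-sample
#' allele depths are taken from the `AD` genotype field and multiallelic
#' records are split into one row per alternate allele.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @param sample sample id to assign to VCF records when the VCF has a
#'   single unnamed genotype column.
#' @return `data.frame` of mutation observations.
#' @export
readVariants <- function(path, format = c("auto", "tsv", "vcf"), sample = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    x <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "t_alt_count", "t_ref_count")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop(path, ": missing required columns: ", paste(miss, collapse = ", "),
           " (expected ", paste(need, collapse = ", "), ")")
    bad <- which(x$pos < 1)
    if (length(bad))
      stop(path, ": positions must be 1-based (>= 1); offending line(s): ",
           paste(bad, collapse = ", "))
    if (any(x$t_alt_count < 0 | x$t_ref_count < 0))
      stop(path, ": negative read counts")
    return(x)
  }
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)     # split multiallelics
  rr <- SummarizedExperiment::rowRanges(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop(path, ": VCF lacks the AD genotype field")
  sampleIds <- colnames(vcf)
  if (length(sampleIds) == 1L && !is.null(sample)) sampleIds <- sample
  out <- list(); dropped <- 0L
  for (s in seq_along(sampleIds)) {
    if (length(dim(ad)) == 3L) {           # Number=R expands to ref/alt slices
      refc <- ad[, s, 1]
      altc <- ad[, s, 2]
    } else {
      depths <- ad[, s]
      refc <- vapply(depths, function(d) if (length(d) >= 2) d[1] else NA_integer_, 0L)
      altc <- vapply(depths, function(d) if (length(d) >= 2) d[2] else NA_integer_, 0L)
    }
    keep <- !is.na(refc) & !is.na(altc)
    dropped <- dropped + sum(!keep)
    out[[s]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr))[keep],
      pos = GenomicRanges::start(rr)[keep],
      ref = as.character(rr$REF)[keep],
      alt = as.character(rr$ALT)[keep],
      sample = sampleIds[s],
      t_alt_count = altc[keep], t_ref_count = refc[keep],
      stringsAsFactors = FALSE)
  }
  if (dropped) warning(path, ": ", dropped, " record(s) dropped for missing AD depths")
  do.call(rbind, out)
}

#' Read the per-sample metadata table
#'
#' @param path TSV with columns sample, patient, day, purity, alc_per_ul.
#' @return `data.frame` ordered by day.
#' @export
readSamples <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "day", "purity", "alc_per_ul")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(path, ": missing required columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$alc_per_ul < 0)) stop(path, ": alc_per_ul must be non-negative")
  if (any(x$purity <= 0 | x$purity > 1)) stop(path, ": purity must lie in (0, 1]")
  key <- paste(x$patient %||% "", x$day)
  if (anyDuplicated(key)) stop(path, ": duplicated (patient, day)")
  x[order(x$day), , drop = FALSE]
}

#' Read an allele-specific copy-number segment table
#'
#' @param path SEG-like TSV with columns sample, chrom, start, end (1-based
#'   inclusive), total_cn, minor_cn.
#' @return `data.frame`.
#' @export
readSegments <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(path, ": missing required columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$start < 1) || any(x$end < x$start))
    stop(path, ": segments must satisfy 1 <= start <= end (1-based inclusive)")
  x
}

#' Annotate mutations with local copy number from segments
#'
#' Overlap join (1-based inclusive on both sides) assigning each mutation
#' its sample's segment `total_cn`/`minor_cn`; positions not covered by any
#' segment default to diploid (2/1).
#'
#' @param mutations mutation `data.frame` (chrom, pos, sample).
#' @param segments segment `data.frame` from [readSegments()].
#' @return `mutations` with `total_cn` and `minor_cn` columns filled.
#' @export
annotateCopyNumber <- function(mutations, segments) {
  mutations <- as.data.frame(mutations)
  mutations$total_cn <- 2L
  mutations$minor_cn <- 1L
  mg <- GenomicRanges::GRanges(mutations$chrom,
                               IRanges::IRanges(mutations$pos, mutations$pos))
  for (s in unique(mutations$sample)) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    if (!nrow(seg)) next
    sg <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
    idx <- which(mutations$sample == s)
    hits <- GenomicRanges::findOverlaps(mg[idx], sg, select = "first")
    hit <- !is.na(hits)
    mutations$total_cn[idx[hit]] <- seg$total_cn[hits[hit]]
    if ("minor_cn" %in% names(seg))
      mutations$minor_cn[idx[hit]] <- seg$minor_cn[hits[hit]]
  }
  mutations
}

#' Read a key = value pipeline configuration file
#'
#' Plain-text configuration with one `key = value` per line; `#` starts a
#' comment. Unknown keys are errors. Defaults are filled for every optional
#' key; `seed` is mandatory.
#'
#' @param path configuration file.
#' @return Named list with the full configuration (see [runPipeline()]).
#' @export
readPipelineConfig <- function(path) {
  defaults <- list(mutations = NULL, segments = NULL, samples = NULL,
                   blood_volume_l = 5, grid_step = 0.001, k_max = 6,
                   epsilon = 0.10, detection_ccf = 0.01,
                   upper_bound_fraction = 0.01, mc_draws = 1000,
                   seed = NULL, ccf_mode = "exclusive")
  numericKeys <- c("blood_volume_l", "grid_step", "k_max", "epsilon",
                   "detection_ccf", "upper_bound_fraction", "mc_draws", "seed")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop(path, ": malformed line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) stop(path, ": unknown configuration key: ", key)
    cfg[[key]] <- if (key %in% numericKeys) as.numeric(val) else val
  }
  if (is.null(cfg$seed)) stop(path, ": seed is mandatory")
  fr <- c("grid_step", "detection_ccf", "upper_bound_fraction", "epsilon")
  for (k in fr) if (cfg[[k]] <= 0 || cfg[[k]] >= 1)
    stop(path, ": ", k, " must lie in (0, 1)")
  if (!cfg$ccf_mode %in% c("exclusive", "inclusive"))
    stop(path, ": ccf_mode must be 'exclusive' or 'inclusive'")
  cfg
}

#' Write a tabular report deterministically
#'
#' @param x `data.frame`-like table.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writeReportTable <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
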