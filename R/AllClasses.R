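## Central S4 containers.  Genomic objects wrap GRanges; the per-sample
## signal container wraps RangedSummarizedExperiment so that assays stay
## aligned to the probe manifest.

GENOTYPE_LEVELS <- c("AA", "AB", "BB")
HMM_STATES <- c("CN0", "CN1", "CN2", "CN2-LOH", "CN3", "CN4")
HMM_COPYNUMBER <- c(CN0 = 0L, CN1 = 1L, CN2 = 2L, `CN2-LOH` = 2L,
                    CN3 = 3L, CN4 = 4L)

#' SnpManifest: ordered probe manifest
#'
#' A [GenomicRanges::GRanges] subclass holding one width-1 range per probe,
#' sorted by position within chromosome, with metadata columns `Name`
#' (unique probe identifier), `GC` (local GC fraction in \[0, 1\]) and,
#' for synthetic manifests, `FreqB` (the generating B-allele frequency).
#'
#' @param names character vector of unique probe names.
#' @param chrom chromosome name(s), recycled.
#' @param positions 1-based probe positions, strictly increasing within
#'   each chromosome.
#' @param gc local GC fraction per probe, in \[0, 1\].
#' @param freqB optional generating B-allele frequency per probe.
#' @return A `SnpManifest` object.
#' @export
#' @examples
#' SnpManifest(c("rs1", "rs2"), "chr5", c(100L, 200L), c(0.4, 0.5))
setClass("SnpManifest", contains = "GRanges")

#' @rdname SnpManifest-class
#' @export
SnpManifest <- function(names, chrom, positions, gc, freqB = NULL) {
  gr <- GRanges(seqnames = chrom,
                ranges = IRanges(start = as.integer(positions), width = 1L))
  mcols(gr)$Name <- as.character(names)
  mcols(gr)$GC <- as.numeric(gc)
  if (!is.null(freqB)) mcols(gr)$FreqB <- as.numeric(freqB)
  new("SnpManifest", gr)
}

setValidity("SnpManifest", function(object) {
  msg <- character()
  mc <- mcols(object)
  if (!all(c("Name", "GC") %in% colnames(mc)))
    msg <- c(msg, "metadata columns 'Name' and 'GC' are required")
  else {
    if (anyDuplicated(mc$Name)) msg <- c(msg, "probe names must be unique")
    if (any(mc$GC < 0 | mc$GC > 1, na.rm = TRUE))
      msg <- c(msg, "GC fractions must lie in [0, 1]")
  }
  pos <- start(object)
  for (chr in unique(as.character(seqnames(object)))) {
    p <- pos[as.character(seqnames(object)) == chr]
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, sprintf("positions on %s must be strictly increasing", chr))
  }
  if (length(msg)) msg else TRUE
})

#' SnpSignalSet: per-sample, per-probe signal container
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass whose rows
#' are the probes of a [SnpManifest] and whose columns are samples.  Known
#' assays: `X`, `Y` (raw intensities), `theta`, `R` (polar coordinates on
#' the log10 scale), `genotype` (integer copies of the B allele, `NA` for
#' no-calls), `genoConf` (call confidence, smaller is better), `baf`, `lrr`.
#' `colData` carries at least a `label` column (`"case"`/`"control"`).
#'
#' @param manifest a [SnpManifest].
#' @param assays named list of probe-by-sample matrices.
#' @param colData a `DataFrame` of per-sample annotation (needs `label`).
#' @param metadata optional list stored in the object metadata (e.g.
#'   simulation truth).
#' @return A `SnpSignalSet`.
#' @export
setClass("SnpSignalSet",
         contains = "RangedSummarizedExperiment")

#' @rdname SnpSignalSet-class
#' @export
SnpSignalSet <- function(manifest, assays, colData, metadata = list()) {
  se <- SummarizedExperiment(assays = assays, rowRanges = manifest,
                             colData = colData, metadata = metadata)
  rownames(se) <- mcols(manifest)$Name
  new("SnpSignalSet", se)
}

setValidity("SnpSignalSet", function(object) {
  msg <- character()
  known <- c("X", "Y", "theta", "R", "genotype", "genoConf", "baf", "lrr",
             "total", "log2ratio")
  bad <- setdiff(assayNames(object), known)
  if (length(bad))
    msg <- c(msg, paste("unknown assay(s):", paste(bad, collapse = ", ")))
  if ("baf" %in% assayNames(object)) {
    rng <- suppressWarnings(range(assay(object, "baf"), na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "baf values must lie in [0, 1]")
  }
  if ("theta" %in% assayNames(object)) {
    rng <- suppressWarnings(range(assay(object, "theta"), na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "theta values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SnpSignalSet-class the probe manifest of the set.
#' @param x,object a `SnpSignalSet`.
#' @export
snpManifest <- function(x) {
  gr <- rowRanges(x)
  if (!is(gr, "SnpManifest")) gr <- new("SnpManifest", gr)
  gr
}

#' @describeIn SnpSignalSet-class case/control label per sample.
#' @export
sampleLabels <- function(x) setNames(as.character(colData(x)$label),
                                     colnames(x))

#' GenotypeClusters: canonical per-SNP genotype clusters
#'
#' Per-SNP AA/AB/BB cluster centers in polar (theta, R) space, with member
#' counts, a usability flag and imputation markers.  Built by
#' [buildClusters()].
#'
#' @slot snp probe names, aligned to the manifest.
#' @slot theta,R numeric matrices (probes x AA/AB/BB) of cluster centers.
#' @slot counts integer matrix of member counts per cluster.
#' @slot usable logical; `TRUE` where the SNP supports BAF/LRR derivation.
#' @slot imputed logical matrix marking imputed cluster components.
#' @export
setClass("GenotypeClusters",
         representation(snp = "character", theta = "matrix", R = "matrix",
                        counts = "matrix", usable = "logical",
                        imputed = "matrix"))

setValidity("GenotypeClusters", function(object) {
  m <- length(object@snp)
  dims_ok <- all(vapply(list(object@theta, object@R, object@counts,
                             object@imputed),
                        function(x) nrow(x) == m && ncol(x) == 3L,
                        logical(1)))
  if (!dims_ok) return("all matrices must be probes x 3 (AA/AB/BB)")
  if (length(object@usable) != m) return("usable flag length mismatch")
  u <- which(object@usable)
  if (length(u)) {
    th <- object@theta[u, , drop = FALSE]
    if (any(!(th[, 1] < th[, 2] & th[, 2] < th[, 3])))
      return("usable SNPs must have theta_AA < theta_AB < theta_BB")
    if (any(object@R[u, ] <= 0))
      return("usable SNPs must have positive cluster R")
  }
  TRUE
})

#' @describeIn GenotypeClusters-class fraction of SNPs usable for
#'   BAF/LRR derivation.
#' @param object a `GenotypeClusters`.
#' @export
usableFraction <- function(object) mean(object@usable)

setMethod("show", "GenotypeClusters", function(object) {
  cat(sprintf("GenotypeClusters: %d SNPs, %.1f%% usable, %d imputed components\n",
              length(object@snp), 100 * usableFraction(object),
              sum(object@imputed)))
})

#' CnvHmm: six-state copy-number hidden Markov model
#'
#' States `CN0, CN1, CN2, CN2-LOH, CN3, CN4` emitting (LRR, BAF) pairs,
#' with distance-dependent transitions (see [transitionMatrix()]).
#'
#' @slot states the ordered state names.
#' @slot lrrMean,lrrSd per-state LRR emission mean and SD.
#' @slot bafSd SD of the interior BAF genotype bands.
#' @slot transBase 6x6 row-stochastic base transition matrix (large-distance
#'   limit before the distance factor is applied).
#' @slot distScale distance scale D (bp) of the transition decay.
#' @slot outlierFrac probability mass of the uniform outlier component mixed
#'   into every emission density (robustness against single-probe spikes).
#' @export
setClass("CnvHmm",
         representation(states = "character", lrrMean = "numeric",
                        lrrSd = "numeric", bafSd = "numeric",
                        transBase = "matrix", distScale = "numeric",
                        outlierFrac = "numeric"))

setValidity("CnvHmm", function(object) {
  msg <- character()
  if (!identical(object@states, HMM_STATES))
    msg <- c(msg, "states must be CN0, CN1, CN2, CN2-LOH, CN3, CN4")
  if (length(object@lrrMean) != 6L || length(object@lrrSd) != 6L)
    msg <- c(msg, "lrrMean and lrrSd must have length 6")
  else {
    mu <- object@lrrMean
    if (!(mu[1] < mu[2] && mu[2] < mu[3] && mu[3] == mu[4] &&
          mu[4] < mu[5] && mu[5] < mu[6]))
      msg <- c(msg, "lrrMean must be ordered CN0 < CN1 < CN2 = CN2-LOH < CN3 < CN4")
    if (any(object@lrrSd <= 0)) msg <- c(msg, "lrrSd must be positive")
  }
  if (length(object@bafSd) != 1L || object@bafSd <= 0)
    msg <- c(msg, "bafSd must be a positive scalar")
  tb <- object@transBase
  if (!all(dim(tb) == c(6L, 6L)) || any(tb < 0) ||
      any(abs(rowSums(tb) - 1) > 1e-8))
    msg <- c(msg, "transBase must be 6x6 row-stochastic")
  if (object@distScale <= 0) msg <- c(msg, "distScale must be positive")
  if (object@outlierFrac < 0 || object@outlierFrac >= 1)
    msg <- c(msg, "outlierFrac must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CnvHmm", function(object) {
  cat("CnvHmm (6 states, distance-aware transitions)\n")
  cat("  lrrMean:", paste(sprintf("%s=%.2f", object@states, object@lrrMean),
                          collapse = " "), "\n")
  cat(sprintf("  bafSd=%.3f distScale=%g bp outlierFrac=%.3f\n",
              object@bafSd, object@distScale, object@outlierFrac))
})

#' CnvCalls: called copy-number segments
#'
#' A [GenomicRanges::GRanges] subclass with 1-based inclusive segment
#' coordinates and metadata columns `sample`, `state`, `cn`, `numsnp`,
#' `startSnp`, `endSnp`, `conf` (log10 likelihood ratio of the decoded
#' path versus the same path forced diploid across the segment).
#'
#' @export
setClass("CnvCalls", contains = "GRanges")

setValidity("CnvCalls", function(object) {
  need <- c("sample", "state", "cn", "numsnp", "conf")
  if (!all(need %in% colnames(mcols(object))))
    return(paste("metadata columns required:", paste(need, collapse = ", ")))
  if (length(object)) {
    if (any(mcols(object)$numsnp < 1L)) return("numsnp must be >= 1")
    if (any(width(object) < 1L)) return("segment length must be >= 1 bp")
    if (any(mcols(object)$state == "CN2"))
      return("plain diploid segments are not calls")
  }
  TRUE
})

#' CnvRegions: associated copy-number variable regions
#'
#' A [GenomicRanges::GRanges] subclass holding case-control associated
#' regions with metadata columns `peakSnp`, `peakPos`, `nSnps`,
#' `caseCarriers`, `ctrlCarriers`, `caseIds` (CharacterList), `pFisher`,
#' `pPerm`, `exclusive`, and exclusion flags `flagTelomereCentromere`,
#' `flagPeninsula`, `flagGcExtreme`, `flagMultiCnvr`.
#'
#' @export
setClass("CnvRegions", contains = "GRanges")

setValidity("CnvRegions", function(object) {
  need <- c("peakSnp", "peakPos", "caseCarriers", "ctrlCarriers", "pFisher",
            "exclusive")
  if (!all(need %in% colnames(mcols(object))))
    return(paste("metadata columns required:", paste(need, collapse = ", ")))
  if (length(object)) {
    mc <- mcols(object)
    if (any(mc$peakPos < start(object) | mc$peakPos > end(object)))
      return("peak position must lie inside the region")
    if (!identical(as.logical(mc$exclusive), mc$ctrlCarriers == 0L))
      return("exclusive flag must mirror ctrlCarriers == 0")
  }
  TRUE
})

#' CarrierMatrix: per-SNP CNV carrier tabulation
#'
#' Per SNP, per group (case/control), per CNV type (dup/del) carrier counts
#' and carrier sample identifiers, together with group sizes.  Built by
#' [carrierMatrix()].
#'
#' @slot manifest the [SnpManifest] the counts are aligned to.
#' @slot counts integer array `probes x c(case, control) x c(dup, del)`.
#' @slot carriers list `dup`/`del`, each with `case`/`control`
#'   [IRanges::CharacterList] of carrier ids per SNP.
#' @slot nCase,nCtrl group sizes.
#' @export
setClass("CarrierMatrix",
         representation(manifest = "SnpManifest", counts = "array",
                        carriers = "list", nCase = "integer",
                        nCtrl = "integer"))

setValidity("CarrierMatrix", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L || d[1] != length(object@manifest) ||
      d[2] != 2L || d[3] != 2L)
    return("counts must be probes x 2 groups x 2 types")
  if (any(object@counts[, 1, ] > object@nCase) ||
      any(object@counts[, 2, ] > object@nCtrl))
    return("carrier counts cannot exceed group sizes")
  TRUE
})

setMethod("show", "CarrierMatrix", function(object) {
  cat(sprintf("CarrierMatrix: %d SNPs, %d cases / %d controls; max dup carriers %d (case) %d (control)\n",
              length(object@manifest), object@nCase, object@nCtrl,
              max(object@counts[, 1, 1]), max(object@counts[, 2, 1])))
})
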