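## End-to-end orchestration: normalize -> (optional) train -> call -> QC
## -> size filter -> associate -> permute -> report.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default.  Input data may be
#' given either in memory (`cohort`, a [SnpSignalSet] with raw assays, or
#' a [SimulationConfig] under `simulate`) or as paths (`manifestPath`,
#' `signalDir`, `labelsPath`).
#'
#' @param simulate optional [SimulationConfig]; when set, the cohort is
#'   generated in memory.
#' @param cohort optional pre-built [SnpSignalSet] with `X`/`Y` (or
#'   `theta`/`R`) and `genotype` assays.
#' @param manifestPath,signalDir,labelsPath file-based inputs (used when
#'   no in-memory cohort is given).
#' @param cytobandPath,commonCnvPath optional annotation inputs for the
#'   exclusion rules.
#' @param outDir optional output directory; when set, the region report,
#'   QC report and call files are written there.
#' @param seed integer seed governing training batches and permutations.
#' @param train run Baum-Welch training before calling.
#' @param model starting [CnvHmm].
#' @param minSnps,minLengthBp size-filter thresholds.
#' @param alpha,mergeWindowBp,nPerm,exclusiveOnly,direction,cnvType
#'   association settings.
#' @return A classed list of settings.
#' @export
pipelineConfig <- function(simulate = NULL, cohort = NULL,
                           manifestPath = NULL, signalDir = NULL,
                           labelsPath = NULL, cytobandPath = NULL,
                           commonCnvPath = NULL, outDir = NULL,
                           seed = 1L, train = FALSE,
                           model = cnvHmmDefaults(),
                           minSnps = 10L, minLengthBp = 1e5,
                           alpha = 0.05, mergeWindowBp = 1e6,
                           nPerm = 10000L, exclusiveOnly = TRUE,
                           direction = "case", cnvType = "dup") {
  structure(list(simulate = simulate, cohort = cohort,
                 manifestPath = manifestPath, signalDir = signalDir,
                 labelsPath = labelsPath, cytobandPath = cytobandPath,
                 commonCnvPath = commonCnvPath, outDir = outDir,
                 seed = as.integer(seed), train = train, model = model,
                 minSnps = minSnps, minLengthBp = minLengthBp,
                 alpha = alpha, mergeWindowBp = mergeWindowBp,
                 nPerm = nPerm, exclusiveOnly = exclusiveOnly,
                 direction = direction, cnvType = cnvType),
            class = "cnvarrayPipelineConfig")
}

.stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full CNV discovery and association pipeline
#'
#' Stages, in order: signal normalization (polar transform, canonical
#' clusters, BAF/LRR, GC-wave correction), optional HMM training, Viterbi
#' CNV calling, sample QC (call rate, LRR noise, GC wave, relatedness,
#' PCA ancestry, CNV count), size filtering, per-SNP association with
#' CNVR formation and exclusion rules, and permutation significance for
#' the reported regions.  Deterministic given the seed.
#'
#' @param config a [pipelineConfig()] list.
#' @return A list with elements `cohort` (the annotated [SnpSignalSet]),
#'   `clusters`, `pfb`, `model`, `qc`, `passSamples`, `calls` (all),
#'   `filteredCalls`, `carriers`, `regions`, and `log` (per-stage counts).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "cnvarrayPipelineConfig"))
  log <- list()

  ## ---- load / generate --------------------------------------------------
  if (!is.null(config$simulate)) {
    manifest <- simulateManifest(config$simulate)
    cohort <- simulateCohort(config$simulate, manifest)
  } else if (!is.null(config$cohort)) {
    cohort <- config$cohort
    manifest <- snpManifest(cohort)
  } else {
    if (is.null(config$manifestPath) || !file.exists(config$manifestPath))
      stop("configuration error: manifest not found at '",
           config$manifestPath %||% "<unset>", "'")
    manifest <- readSnpManifest(config$manifestPath)
    labels <- readLabels(config$labelsPath)
    cohort <- readRawCohort(config$signalDir, manifest, labels)
  }
  labels <- sampleLabels(cohort)
  .stageLog("load", "%d samples (%d cases, %d controls), %d probes",
            ncol(cohort), sum(labels == "case"),
            sum(labels == "control"), nrow(cohort))
  log$samplesIn <- ncol(cohort)

  ## ---- normalize --------------------------------------------------------
  if (!"theta" %in% assayNames(cohort)) cohort <- polarize(cohort)
  clusters <- buildClusters(cohort)
  .stageLog("normalize", "%.1f%% of SNPs usable for clustering",
            100 * usableFraction(clusters))
  log$usableSnpFraction <- usableFraction(clusters)
  cohort <- deriveSignal(cohort, clusters)
  gc <- mcols(manifest)$GC
  assay(cohort, "lrr") <- gcCorrect(assay(cohort, "lrr"), gc)
  ## on large cohorts, keep only the assays later stages use
  if (prod(dim(cohort)) > 5e6) {
    keepAssays <- intersect(c("baf", "lrr", "genotype"), assayNames(cohort))
    assays(cohort) <- assays(cohort)[keepAssays]
    invisible(gc(verbose = FALSE))
  }

  ## ---- qc (sample-level, pre-calling) -----------------------------------
  qc <- qcReport(cohort, calls = NULL, gc = gc)
  passPre <- !qc$excluded
  .stageLog("qc", "%d/%d samples pass pre-call QC", sum(passPre),
            length(passPre))

  ## ---- pfb --------------------------------------------------------------
  pfb <- computePFB(assay(cohort, "baf")[, passPre, drop = FALSE],
                    usable = clusters@usable)

  ## ---- train (optional) -------------------------------------------------
  model <- config$model
  if (isTRUE(config$train)) {
    model <- trainHmm(cohort, pfb, model = model, seed = config$seed)
    .stageLog("train", "trained model: lrrMean CN3 = %.3f", model@lrrMean[5])
  }

  ## ---- call -------------------------------------------------------------
  passIds <- colnames(cohort)[passPre]
  calls <- callCnvs(cohort, pfb, model = model, samples = passIds)
  .stageLog("call", "%d raw CNV calls in %d samples", length(calls),
            length(unique(mcols(calls)$sample)))
  log$rawCalls <- length(calls)

  ## ---- qc (CNV count) ---------------------------------------------------
  passCnv <- cnvCountFilter(calls, samples = passIds)
  failCnv <- passIds[!passCnv]
  passIds <- passIds[passCnv]
  calls <- new("CnvCalls", calls[mcols(calls)$sample %in% passIds])
  qc$passCnvCount <- !(rownames(qc) %in% failCnv)
  qc$excluded <- qc$excluded | !qc$passCnvCount
  .stageLog("qc", "%d samples pass all QC", length(passIds))
  log$samplesPass <- length(passIds)

  ## ---- size filter ------------------------------------------------------
  filtered <- sizeFilter(calls, minSnps = config$minSnps,
                         minLength = config$minLengthBp)
  .stageLog("filter", "%d calls of >= %d SNPs and >= %g bp",
            length(filtered), config$minSnps, config$minLengthBp)
  log$filteredCalls <- length(filtered)

  ## ---- associate --------------------------------------------------------
  passLabels <- labels[passIds]
  carriers <- carrierMatrix(filtered, manifest, passLabels)
  regions <- formCnvrs(carriers, type = config$cnvType,
                       alpha = config$alpha,
                       mergeWindow = config$mergeWindowBp,
                       exclusiveOnly = config$exclusiveOnly,
                       direction = config$direction)
  cytobands <- if (!is.null(config$cytobandPath))
    readCytoband(config$cytobandPath) else NULL
  commonCnv <- if (!is.null(config$commonCnvPath))
    readCnvBed(config$commonCnvPath) else NULL
  if (!is.null(commonCnv)) {
    mcols(commonCnv)$freq <- 1  # caller-provided track is already common
  }
  regions <- applyExclusionRules(regions, cytobands = cytobands,
                                 manifest = manifest,
                                 commonCnv = commonCnv)
  .stageLog("assoc", "%d region(s) reported", length(regions))
  log$regions <- length(regions)

  ## ---- permute ----------------------------------------------------------
  if (length(regions)) {
    pP <- vapply(seq_along(regions), function(i) {
      permutationTest(unlist(mcols(regions)$caseIds[i]), passLabels,
                      nPerm = config$nPerm,
                      seed = config$seed + i)$p
    }, numeric(1))
    mcols(regions)$pPerm <- pP
  }

  ## ---- report -----------------------------------------------------------
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("# cnvarray %s | seed %d",
                   as.character(utils::packageVersion("cnvarray")),
                   config$seed)
    rf <- file.path(config$outDir, "regions.tsv")
    mc <- mcols(regions)
    df <- data.frame(Region = sprintf("%s:%d-%d",
                                      as.character(seqnames(regions)),
                                      start(regions), end(regions)),
                     PeakSNP = mc$peakSnp, nSNPs = mc$nSnps,
                     CaseCarriers = mc$caseCarriers,
                     ControlCarriers = mc$ctrlCarriers,
                     CaseIDs = vapply(mc$caseIds, paste, character(1),
                                      collapse = ";"),
                     pFisher = mc$pFisher, pPerm = mc$pPerm,
                     Excluded = mc$anyFlag)
    writeLines(hdr, rf)
    suppressWarnings(write.table(df, rf, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    write.table(as.data.frame(qc),
                file.path(config$outDir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = TRUE)
    writeRawCnv(filtered, file.path(config$outDir, "calls.rawcnv"))
    writeCnvBed(filtered, file.path(config$outDir, "calls.bed"))
  }

  list(cohort = cohort, clusters = clusters, pfb = pfb, model = model,
       qc = qc, passSamples = passIds, calls = calls,
       filteredCalls = filtered, carriers = carriers, regions = regions,
       log = log)
}
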