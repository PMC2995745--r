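## Case-control CNV association: size filtering, per-SNP carrier
## tabulation, one-sided Fisher tests, exclusivity screening, CNVR
## formation with local-minimum narrowing, exclusion rules, permutation
## significance, and the control-contamination estimate.

#' Size-filter CNV calls
#'
#' Keeps calls with at least `minSnps` probes and at least `minLength` bp
#' (both inclusive).  Loss-of-heterozygosity calls (`cn == 2`) are not
#' copy-number changes and are dropped.
#'
#' @param calls a [CnvCalls].
#' @param minSnps minimum probe count (inclusive).
#' @param minLength minimum length in bp (inclusive).
#' @return The filtered [CnvCalls].
#' @export
sizeFilter <- function(calls, minSnps = 10L, minLength = 1e5) {
  keep <- mcols(calls)$numsnp >= minSnps & width(calls) >= minLength &
    mcols(calls)$cn != 2L
  new("CnvCalls", calls[keep])
}

#' Per-SNP carrier tabulation
#'
#' A sample is a carrier at a SNP for a CNV type (duplication `cn > 2`,
#' deletion `cn < 2`) iff it has at least one call of that type whose
#' 1-based inclusive interval contains the SNP position; overlapping calls
#' in one sample count once.
#'
#' @param calls a [CnvCalls] (usually size-filtered).
#' @param manifest a [SnpManifest].
#' @param labels named character vector (`"case"`/`"control"`) covering
#'   every sample appearing in `calls` — unlabeled samples are an error —
#'   whose length defines the group sizes.
#' @return A [CarrierMatrix].
#' @export
carrierMatrix <- function(calls, manifest, labels) {
  samp <- as.character(mcols(calls)$sample)
  if (!all(samp %in% names(labels)))
    stop("unlabeled sample(s) in calls: ",
         paste(head(setdiff(samp, names(labels))), collapse = ", "))
  m <- length(manifest)
  counts <- array(0L, c(m, 2L, 2L),
                  dimnames = list(NULL, c("case", "control"),
                                  c("dup", "del")))
  carriers <- list(dup = list(case = NULL, control = NULL),
                   del = list(case = NULL, control = NULL))
  for (type in c("dup", "del")) {
    sel <- if (type == "dup") mcols(calls)$cn > 2L else mcols(calls)$cn < 2L
    sub <- calls[sel]
    hits <- findOverlaps(manifest, sub)
    snpOf <- queryHits(hits)
    sampOf <- samp[sel][subjectHits(hits)]
    keep <- !duplicated(paste(snpOf, sampOf))   # per-sample dedup per SNP
    snpOf <- snpOf[keep]; sampOf <- sampOf[keep]
    grp <- labels[sampOf]
    for (g in c("case", "control")) {
      idx <- grp == g
      counts[, g, type] <- tabulate(snpOf[idx], nbins = m)
      cl <- split(sampOf[idx], factor(snpOf[idx], levels = seq_len(m)))
      carriers[[type]][[g]] <- as(cl, "CharacterList")
    }
  }
  new("CarrierMatrix", manifest = manifest, counts = counts,
      carriers = carriers,
      nCase = sum(labels == "case"), nCtrl = sum(labels == "control"))
}

#' One-sided Fisher exact test for case carrier enrichment
#'
#' Exact hypergeometric tail probability of observing at least `a` case
#' carriers given `a + b` carriers total, computed in log space so very
#' large cohorts do not overflow.  Vectorized over `a` and `b`.
#'
#' @param a case carrier count(s).
#' @param nCase number of cases.
#' @param b control carrier count(s).
#' @param nCtrl number of controls.
#' @return One-sided p-value(s) toward case enrichment.
#' @export
fisherCarrier <- function(a, nCase, b, nCtrl) {
  stopifnot(all(a <= nCase), all(b <= nCtrl))
  vapply(seq_along(a), function(i) {
    k <- a[i] + b[i]
    if (k == 0L) return(1)
    hi <- min(k, nCase)
    if (a[i] == 0L) return(1)
    j <- a[i]:hi
    lp <- lchoose(nCase, j) + lchoose(nCtrl, k - j) - lchoose(nCase + nCtrl, k)
    mx <- max(lp)
    min(1, exp(mx + log(sum(exp(lp - mx)))))
  }, numeric(1))
}

#' Form CNV regions from per-SNP association
#'
#' SNPs with `p < alpha` are merged into one region while consecutive
#' significant SNPs lie within `mergeWindow` of each other; the region
#' peak is the SNP with the minimal p (ties: leftmost), the statistical
#' local minimum that narrows the association.  With `exclusiveOnly`,
#' only regions with zero control carriers at the peak are reported.
#'
#' @param cm a [CarrierMatrix].
#' @param type `"dup"`, `"del"`, or `"any"` (dup and del carriers pooled).
#' @param alpha per-SNP significance threshold.
#' @param mergeWindow maximum gap (bp) between significant SNPs in one
#'   region.
#' @param exclusiveOnly report only case-exclusive regions.
#' @param direction `"case"` tests case enrichment, `"control"` the
#'   reverse.
#' @return A [CnvRegions] (zero-length when nothing is significant).
#' @export
formCnvrs <- function(cm, type = c("dup", "del", "any"), alpha = 0.05,
                      mergeWindow = 1e6, exclusiveOnly = TRUE,
                      direction = c("case", "control")) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  man <- cm@manifest
  if (type == "any") {
    aCnt <- pmin(cm@counts[, 1, "dup"] + cm@counts[, 1, "del"], cm@nCase)
    bCnt <- pmin(cm@counts[, 2, "dup"] + cm@counts[, 2, "del"], cm@nCtrl)
  } else {
    aCnt <- cm@counts[, 1, type]
    bCnt <- cm@counts[, 2, type]
  }
  p <- if (direction == "case") fisherCarrier(aCnt, cm@nCase, bCnt, cm@nCtrl)
       else fisherCarrier(bCnt, cm@nCtrl, aCnt, cm@nCase)

  sig <- which(p < alpha)
  gr0 <- GRanges()
  mcols(gr0) <- DataFrame(
    peakSnp = character(), peakPos = integer(), nSnps = integer(),
    caseCarriers = integer(), ctrlCarriers = integer(),
    caseIds = CharacterList(), pFisher = numeric(), pPerm = numeric(),
    exclusive = logical())
  empty <- new("CnvRegions", gr0)
  if (!length(sig)) return(empty)

  pos <- start(man)
  chr <- as.character(seqnames(man))
  ## split significant SNPs into regions on chromosome change or gaps
  brk <- c(TRUE, diff(pos[sig]) > mergeWindow |
             chr[sig][-1] != chr[sig][-length(sig)])
  grpId <- cumsum(brk)
  regs <- lapply(split(sig, grpId), function(idx) {
    peak <- idx[which.min(p[idx])]        # which.min takes the leftmost tie
    caseIds <- if (type == "any")
      unique(c(unlist(cm@carriers$dup$case[peak]),
               unlist(cm@carriers$del$case[peak])))
    else unlist(cm@carriers[[type]]$case[peak])
    GRanges(chr[idx[1]], IRanges(pos[idx[1]], pos[idx[length(idx)]]),
            peakSnp = mcols(man)$Name[peak], peakPos = pos[peak],
            nSnps = length(idx),
            caseCarriers = aCnt[peak], ctrlCarriers = bCnt[peak],
            caseIds = CharacterList(list(sort(caseIds))),
            pFisher = p[peak], pPerm = NA_real_,
            exclusive = bCnt[peak] == 0L)
  })
  gr <- do.call(c, unname(regs))
  if (exclusiveOnly) gr <- gr[mcols(gr)$exclusive]
  if (!length(gr)) return(empty)
  gr <- gr[order(mcols(gr)$pFisher)]
  new("CnvRegions", gr)
}

#' Apply CNVR exclusion rules
#'
#' Four flags mark regions likely to be artifacts: (i) span intersecting
#' an arm-terminal cytoband (telomere or centromere proximal) or a band
#' staining `acen`/`gvar`; (ii) a boundary within `peninsulaWindow` of the
#' same-side boundary of a common CNV (population frequency > 1%) — the
#' "peninsula" of boundary truncation; (iii) mean probe GC outside
#' `gcRange`; (iv) a contributing sample also contributing to another
#' reported region.
#'
#' @param regions a [CnvRegions].
#' @param cytobands UCSC-style cytoband `GRanges` (with `name` and
#'   `gieStain` columns), or `NULL` (rule i reported `NA`).
#' @param manifest the [SnpManifest] (for the GC track).
#' @param commonCnv `GRanges` of common-CNV intervals with a `freq`
#'   column, or `NULL` (rule ii reported `FALSE`).
#' @param peninsulaWindow boundary-adjacency window in bp.
#' @param gcRange acceptable mean-GC interval.
#' @return The regions with logical columns `flagTelomereCentromere`,
#'   `flagPeninsula`, `flagGcExtreme`, `flagMultiCnvr` and `anyFlag`.
#' @export
applyExclusionRules <- function(regions, cytobands = NULL, manifest,
                                commonCnv = NULL, peninsulaWindow = 5e4,
                                gcRange = c(0.30, 0.60)) {
  n <- length(regions)
  flagTel <- rep(NA, n); flagPen <- rep(FALSE, n)
  flagGc <- rep(FALSE, n); flagMulti <- rep(FALSE, n)

  if (!is.null(cytobands) && n) {
    mc <- mcols(cytobands)
    arm <- paste(as.character(seqnames(cytobands)),
                 substr(mc$name, 1, 1))
    terminal <- logical(length(cytobands))
    for (a in unique(arm)) {
      idx <- which(arm == a)
      idx <- idx[order(start(cytobands)[idx])]
      terminal[idx[c(1L, length(idx))]] <- TRUE
    }
    bad <- cytobands[terminal | mc$gieStain %in% c("acen", "gvar")]
    flagTel <- overlapsAny(regions, bad)
  }

  if (!is.null(commonCnv) && n) {
    common <- commonCnv[mcols(commonCnv)$freq > 0.01]
    if (length(common)) {
      sameChr <- outer(as.character(seqnames(regions)),
                       as.character(seqnames(common)), "==")
      dStart <- abs(outer(start(regions), start(common), "-"))
      dEnd <- abs(outer(end(regions), end(common), "-"))
      flagPen <- rowSums(sameChr &
                           (dStart <= peninsulaWindow |
                            dEnd <= peninsulaWindow)) > 0
    }
  }

  if (n) {
    hits <- findOverlaps(regions, manifest)
    meanGc <- vapply(seq_len(n), function(i) {
      g <- mcols(manifest)$GC[subjectHits(hits)[queryHits(hits) == i]]
      if (length(g)) mean(g) else NA_real_
    }, numeric(1))
    flagGc <- !is.na(meanGc) & (meanGc < gcRange[1] | meanGc > gcRange[2])

    ids <- mcols(regions)$caseIds
    for (i in seq_len(n)) {
      others <- unlist(ids[-i])
      flagMulti[i] <- any(unlist(ids[i]) %in% others)
    }
  }

  mcols(regions)$flagTelomereCentromere <- flagTel
  mcols(regions)$flagPeninsula <- flagPen
  mcols(regions)$flagGcExtreme <- flagGc
  mcols(regions)$flagMultiCnvr <- flagMulti
  mcols(regions)$anyFlag <- (!is.na(flagTel) & flagTel) | flagPen |
    flagGc | flagMulti
  regions
}

#' Permutation significance for a CNV region
#'
#' Case/control labels are permuted; the default statistic is the number
#' of the region's carriers assigned to pseudo-cases, set to zero whenever
#' any carrier lands in pseudo-controls (the exclusivity requirement).
#' The empirical p uses the +1 correction and is therefore never zero.
#'
#' @param carrierIds sample ids carrying the region.
#' @param labels named `"case"`/`"control"` vector over all samples.
#' @param nPerm number of permutations (< 100 warns).
#' @param seed RNG seed.
#' @return `list(p =, observed =, nPerm =)`.
#' @export
permutationTest <- function(carrierIds, labels, nPerm = 10000L, seed = 1L) {
  if (nPerm < 100L) warning("fewer than 100 permutations; p is unstable")
  n <- length(labels)
  nCase <- sum(labels == "case")
  carrierIdx <- match(carrierIds, names(labels))
  stopifnot(!anyNA(carrierIdx))
  a <- sum(labels[carrierIdx] == "case")
  b <- length(carrierIdx) - a
  obs <- if (b == 0L) a else 0L
  if (obs == 0L) return(list(p = 1, observed = 0L, nPerm = nPerm))
  hits <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      pseudoCase <- sample.int(n, nCase)
      aP <- sum(carrierIdx %in% pseudoCase)
      statP <- if (aP == length(carrierIdx)) aP else 0L
      statP >= obs
    }, logical(1))
  })
  list(p = (1 + sum(hits)) / (nPerm + 1), observed = obs, nPerm = nPerm)
}

#' Expected undiagnosed cases among unscreened controls
#'
#' Applies an assumed population prevalence to control subsets that were
#' never screened for the phenotype, estimating how many latent cases may
#' dilute the control group.
#'
#' @param prevalence population prevalence in \[0, 1\].
#' @param nUnscreened number of unscreened controls.
#' @param nControlsTotal optional total control count, to report the
#'   contaminated fraction.
#' @return `list(expected =, fraction =)` (fraction `NA` when the total is
#'   not given).
#' @export
contaminationEstimate <- function(prevalence, nUnscreened,
                                  nControlsTotal = NULL) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  expected <- round(prevalence * nUnscreened)
  list(expected = expected,
       fraction = if (is.null(nControlsTotal)) NA_real_
                  else expected / nControlsTotal)
}
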