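## Sample-level quality control: call rate, intensity noise, GC waves,
## relatedness (PI_HAT), CNV-count cap, PCA ancestry outliers.
## All threshold comparisons are strict: boundary values fail.

#' Per-sample genotype call rate
#'
#' @param genotype integer matrix (probes x samples); `NA` marks no-calls.
#' @return Named numeric vector of call rates in \[0, 1\].
#' @export
sampleCallRate <- function(genotype) {
  if (nrow(genotype) < 1L) stop("call rate needs at least one SNP")
  colMeans(!is.na(genotype))
}

#' @describeIn sampleCallRate pass/fail at the strict `> threshold` rule.
#' @param threshold minimum call rate (strict inequality).
#' @export
callRateFilter <- function(genotype, threshold = 0.98) {
  sampleCallRate(genotype) > threshold
}

#' Per-sample LRR noise (derivative log-ratio spread)
#'
#' The noise statistic is `sd(diff(lrr)) / sqrt(2)`, which equals the
#' sample SD in expectation for serially independent noise but is robust
#' to genuine copy-number segments (which shift the mean over a large
#' fraction of a short simulated region without reflecting sample
#' quality).
#'
#' @param lrr matrix (probes x samples) of LRR values.
#' @return Named numeric vector of noise SD estimates (`NA` when fewer
#'   than 2 unmasked probes).
#' @export
lrrSd <- function(lrr) {
  apply(lrr, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    if (length(v) == 2L) return(sd(v))
    sd(diff(v)) / sqrt(2)
  })
}

#' @describeIn lrrSd pass/fail at the strict `< threshold` rule; all-masked
#'   samples fail.
#' @param threshold maximum LRR SD (strict inequality).
#' @export
lrrSdFilter <- function(lrr, threshold = 0.25) {
  s <- lrrSd(lrr)
  !is.na(s) & s < threshold
}

#' GC-wave factor and correction
#'
#' Per sample, LRR is regressed on centered local GC by least squares; the
#' wave factor is `slope * sd(GC)`, a dimensionless signed waviness.
#' `gcCorrect()` subtracts the fitted component (idempotent).  A sample
#' passes when its post-correction factor lies strictly inside
#' `(-threshold, threshold)`.
#'
#' @param lrr matrix (probes x samples).
#' @param gc per-probe local GC fraction.
#' @return `gcWaveFactor`: named numeric vector of wave factors (0 by
#'   convention when GC has zero variance).
#' @export
gcWaveFactor <- function(lrr, gc) {
  gcc <- gc - mean(gc)
  ssg <- sum(gcc^2)
  if (ssg <= 0) return(setNames(rep(0, ncol(lrr)), colnames(lrr)))
  slope <- apply(lrr, 2L, function(v) {
    ok <- is.finite(v)
    sum(v[ok] * gcc[ok]) / sum(gcc[ok]^2)
  })
  slope * sd(gcc)
}

#' @rdname gcWaveFactor
#' @return `gcCorrect`: the LRR matrix with the fitted GC component
#'   removed.
#' @export
gcCorrect <- function(lrr, gc) {
  gcc <- gc - mean(gc)
  if (sum(gcc^2) <= 0) return(lrr)
  w <- gcWaveFactor(lrr, gc) / sd(gcc)
  lrr - outer(gcc, w)
}

#' @rdname gcWaveFactor
#' @param threshold pass when `|factor| < threshold` after correction.
#' @export
gcWaveFilter <- function(lrr, gc, threshold = 0.02) {
  abs(gcWaveFactor(gcCorrect(lrr, gc), gc)) < threshold
}

#' CNV call-count filter
#'
#' Samples with an excessive number of CNV calls usually reflect poor DNA
#' quality; pass requires strictly fewer than `threshold` calls.
#'
#' @param calls a [CnvCalls] object (or a GRanges with a `sample` column).
#' @param samples sample ids to report (defaults to those present).
#' @param threshold maximum call count (strict).
#' @return Named logical vector.
#' @export
cnvCountFilter <- function(calls, samples = NULL, threshold = 100L) {
  tab <- table(mcols(calls)$sample)
  samples <- samples %||% names(tab)
  cnt <- setNames(as.integer(tab[samples]), samples)
  cnt[is.na(cnt)] <- 0L
  cnt < threshold
}

## Per-SNP expected IBS probabilities given IBD state (method of moments).
.ibsExpectations <- function(p) {
  q <- 1 - p
  list(e0_z0 = 2 * p^2 * q^2,
       e1_z0 = 4 * p^3 * q + 4 * p * q^3,
       e2_z0 = p^4 + q^4 + 4 * p^2 * q^2,
       e1_z1 = 2 * p^2 * q + 2 * p * q^2,
       e2_z1 = p^3 + q^3 + p^2 * q + p * q^2)
}

.pihatFromCounts <- function(ibs0, ibs1, ibs2, E0z0, E1z0, E2z0, E1z1, E2z1,
                             nObs) {
  z0 <- ibs0 / E0z0
  z1 <- (ibs1 - z0 * E1z0) / E1z1
  z2 <- (ibs2 - z0 * E2z0 - z1 * E2z1) / nObs
  z0 <- pmin(pmax(z0, 0), 1)
  z1 <- pmin(pmax(z1, 0), 1)
  z2 <- pmin(pmax(z2, 0), 1)
  pmin(pmax(z2 + 0.5 * z1, 0), 1)
}

#' Pairwise identity-by-descent proportion (PI_HAT)
#'
#' Method-of-moments IBD estimation from identity-by-state counts given
#' allele frequencies (the standard expected-IBS-given-IBD construction):
#' `PI_HAT = P(IBD=2) + 0.5 * P(IBD=1)`, truncated to \[0, 1\].
#'
#' @param gi,gj integer genotype vectors (B-allele copies, `NA` = no-call).
#' @param freq per-SNP B-allele frequency.
#' @param minOverlap minimum jointly called SNPs; below it the estimate is
#'   undefined (`NA` with a warning).
#' @return PI_HAT in \[0, 1\], or `NA`.
#' @export
piHat <- function(gi, gj, freq, minOverlap = 100L) {
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < minOverlap) {
    warning("insufficient genotype overlap; PI_HAT undefined")
    return(NA_real_)
  }
  gi <- gi[ok]; gj <- gj[ok]; p <- freq[ok]
  ## opposing homozygotes are the only IBS0 pairs
  ibs0 <- sum(abs(gi - gj) == 2L)
  ibs2 <- sum(gi == gj)
  ibs1 <- length(gi) - ibs0 - ibs2
  e <- .ibsExpectations(p)
  .pihatFromCounts(ibs0, ibs1, ibs2, sum(e$e0_z0), sum(e$e1_z0),
                   sum(e$e2_z0), sum(e$e1_z1), sum(e$e2_z1), length(gi))
}

#' All-pairs PI_HAT matrix
#'
#' Computes PI_HAT for every sample pair via indicator-matrix products, on
#' an evenly thinned SNP subset (synthetic SNPs are unlinked, so thinning
#' only trades precision for speed).  Missing genotypes are handled by
#' per-pair overlap-restricted expectations.
#'
#' @param genotype integer matrix (probes x samples).
#' @param freq per-SNP B-allele frequency.
#' @param thin keep every `thin`-th SNP.
#' @return Symmetric samples-x-samples matrix (diagonal `NA`).
#' @export
piHatMatrix <- function(genotype, freq, thin = 5L, chunkSize = 500L) {
  keep <- seq(1L, nrow(genotype), by = thin)
  G <- t(genotype[keep, , drop = FALSE])     # samples x SNPs
  p <- freq[keep]
  n <- nrow(G)
  M <- (!is.na(G)) * 1
  Gz <- G; Gz[is.na(Gz)] <- -9L
  I0 <- (Gz == 0L) * 1; I1 <- (Gz == 1L) * 1; I2 <- (Gz == 2L) * 1
  rm(Gz)
  e <- .ibsExpectations(p)
  complete <- all(M == 1)
  ph <- matrix(NA_real_, n, n,
               dimnames = list(colnames(genotype), colnames(genotype)))
  ## row chunks keep the pairwise temporaries at chunk x n rather than n x n
  for (lo in seq(1L, n, by = chunkSize)) {
    hi <- min(lo + chunkSize - 1L, n)
    r <- lo:hi
    ibs2 <- tcrossprod(I0[r, , drop = FALSE], I0) +
      tcrossprod(I1[r, , drop = FALSE], I1) +
      tcrossprod(I2[r, , drop = FALSE], I2)
    ibs0 <- tcrossprod(I0[r, , drop = FALSE], I2) +
      tcrossprod(I2[r, , drop = FALSE], I0)
    nObs <- tcrossprod(M[r, , drop = FALSE], M)
    ibs1 <- nObs - ibs0 - ibs2
    if (complete) {
      E0z0 <- sum(e$e0_z0); E1z0 <- sum(e$e1_z0); E2z0 <- sum(e$e2_z0)
      E1z1 <- sum(e$e1_z1); E2z1 <- sum(e$e2_z1)
    } else {                    # exact per-pair overlap expectations
      nr <- length(r)
      E0z0 <- tcrossprod(M[r, , drop = FALSE] * rep(e$e0_z0, each = nr), M)
      E1z0 <- tcrossprod(M[r, , drop = FALSE] * rep(e$e1_z0, each = nr), M)
      E2z0 <- tcrossprod(M[r, , drop = FALSE] * rep(e$e2_z0, each = nr), M)
      E1z1 <- tcrossprod(M[r, , drop = FALSE] * rep(e$e1_z1, each = nr), M)
      E2z1 <- tcrossprod(M[r, , drop = FALSE] * rep(e$e2_z1, each = nr), M)
    }
    ph[r, ] <- .pihatFromCounts(ibs0, ibs1, ibs2, E0z0, E1z0, E2z0,
                                E1z1, E2z1, nObs)
  }
  diag(ph) <- NA_real_
  ph
}

#' Exclude one member of each duplicate pair
#'
#' For every pair with `PI_HAT >= threshold`, the member with the lower
#' call rate is excluded (ties broken by sample-id order, keeping the
#' earlier id).  Applied greedily so chains A~B~C leave one member.
#'
#' @param pihat symmetric PI_HAT matrix with sample-id dimnames.
#' @param callRate named call-rate vector for the same samples.
#' @param threshold duplication threshold (default 0.9).
#' @return Character vector of excluded sample ids.
#' @export
dedupeSamples <- function(pihat, callRate, threshold = 0.9) {
  ids <- rownames(pihat)
  excluded <- character()
  repeat {
    keep <- setdiff(ids, excluded)
    sub <- pihat[keep, keep, drop = FALSE]
    hit <- which(sub >= threshold & upper.tri(sub), arr.ind = TRUE)
    if (!nrow(hit)) break
    i <- keep[hit[1, 1]]; j <- keep[hit[1, 2]]
    drop <- if (callRate[i] < callRate[j]) i
            else if (callRate[j] < callRate[i]) j
            else sort(c(i, j))[2]
    excluded <- c(excluded, drop)
  }
  excluded
}

#' PCA ancestry coordinates and outlier exclusion
#'
#' Genotypes are coded 0/1/2, centered by `2 * p_hat` and scaled by
#' `sqrt(2 * p_hat * (1 - p_hat))` per SNP (constant SNPs dropped); the
#' top `K` components of the sample covariance are extracted, and samples
#' beyond `sdThreshold` SDs on any component are removed iteratively (up
#' to `maxRounds` rounds), recomputing the components each round.
#'
#' @param genotype integer matrix (probes x samples); no-calls are mean
#'   imputed for the decomposition.
#' @param K number of components.
#' @param sdThreshold outlier threshold in component SDs.
#' @param maxRounds maximum removal rounds.
#' @return `list(coords =, excluded =, rounds =)`: final samples-x-K score
#'   matrix (excluded samples have `NA` rows), excluded ids, rounds used.
#' @export
pcaOutliers <- function(genotype, K = 10L, sdThreshold = 6, maxRounds = 5L) {
  if (ncol(genotype) < 2L || nrow(genotype) < 2L)
    stop("PCA needs at least 2 samples and 2 SNPs")
  ids <- colnames(genotype) %||% sprintf("s%04d", seq_len(ncol(genotype)))
  active <- ids
  excluded <- character()
  coords <- NULL
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    Gsub <- genotype[, match(active, ids), drop = FALSE]
    sc <- .scaledGenotypes(Gsub)            # samples x SNPs
    ns <- nrow(sc); ms <- ncol(sc)
    K_eff <- max(1L, min(K, ns - 1L, ms - 1L))
    if (ms <= ns) {                          # eigen on the smaller side
      eg <- eigen(crossprod(sc), symmetric = TRUE)
      coords <- sc %*% eg$vectors[, seq_len(K_eff), drop = FALSE]
    } else {
      eg <- eigen(tcrossprod(sc), symmetric = TRUE)
      coords <- eg$vectors[, seq_len(K_eff), drop = FALSE] *
        rep(sqrt(pmax(eg$values[seq_len(K_eff)], 0)), each = ns)
    }
    rownames(coords) <- active
    z <- scale(coords)
    out <- active[apply(abs(z) > sdThreshold, 1L, any)]
    if (!length(out) || rounds >= maxRounds) break
    excluded <- c(excluded, out)
    active <- setdiff(active, out)
  }
  full <- matrix(NA_real_, length(ids), ncol(coords),
                 dimnames = list(ids, paste0("PC", seq_len(ncol(coords)))))
  full[active, ] <- coords
  list(coords = full, excluded = excluded, rounds = rounds)
}

## center/scale genotype columns per SNP; SNPs are rows on input,
## returns probes-in-columns matrix (samples x SNPs) for crossprod use
.scaledGenotypes <- function(G) {
  X <- t(G)                                  # samples x SNPs
  mu <- colMeans(X, na.rm = TRUE)
  X[is.na(X)] <- rep(mu, each = nrow(X))[is.na(X)]
  p <- mu / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  sweep(sweep(X, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), "/")
}

#' Sample QC report
#'
#' Runs every sample-level filter and combines them into one table; a
#' sample is excluded iff at least one reason code is set.
#'
#' @param x a [SnpSignalSet] with `genotype` and `lrr` assays.
#' @param calls optional [CnvCalls] for the CNV-count filter.
#' @param gc per-probe GC (defaults to the manifest's `GC` column).
#' @param pihat optional precomputed PI_HAT matrix (computed from the
#'   genotype assay when `NULL`).
#' @param callRateMin,lrrSdMax,waveMax,cnvCountMax,dupThreshold filter
#'   thresholds (all strict).
#' @param pcaK,pcaSd PCA settings.
#' @return A `DataFrame` with one row per sample: the QC statistics,
#'   per-filter pass flags, `excluded` and a `reasons` string.
#' @export
qcReport <- function(x, calls = NULL, gc = NULL, pihat = NULL,
                     callRateMin = 0.98, lrrSdMax = 0.25, waveMax = 0.02,
                     cnvCountMax = 100L, dupThreshold = 0.9,
                     pcaK = 10L, pcaSd = 6) {
  geno <- assay(x, "genotype")
  lrr <- assay(x, "lrr")
  gc <- gc %||% mcols(rowRanges(x))$GC
  cr <- sampleCallRate(geno)
  noise <- lrrSd(lrr)
  lrrC <- gcCorrect(lrr, gc)
  wavePre <- gcWaveFactor(lrr, gc)
  wavePost <- gcWaveFactor(lrrC, gc)
  passCR <- cr > callRateMin
  passNoise <- !is.na(noise) & noise < lrrSdMax
  passWave <- abs(wavePost) < waveMax
  if (is.null(pihat)) {
    freq <- computePFB(assay(x, "baf"))
    pihat <- piHatMatrix(geno, freq)
  }
  dup <- dedupeSamples(pihat, cr, dupThreshold)
  passDup <- !(colnames(x) %in% dup)
  maxPartner <- apply(pihat, 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  pca <- pcaOutliers(geno, K = pcaK, sdThreshold = pcaSd)
  passPca <- !(colnames(x) %in% pca$excluded)
  if (!is.null(calls)) {
    passCnv <- cnvCountFilter(calls, samples = colnames(x),
                              threshold = cnvCountMax)
    cnvCount <- table(factor(mcols(calls)$sample, levels = colnames(x)))
  } else {
    passCnv <- rep(TRUE, ncol(x))
    cnvCount <- rep(NA_integer_, ncol(x))
  }
  pass <- cbind(callRate = passCR, lrrSd = passNoise, gcWave = passWave,
                duplicate = passDup, pca = passPca,
                cnvCount = as.logical(passCnv))
  reasons <- apply(pass, 1L, function(p)
    paste(colnames(pass)[!p], collapse = ","))
  DataFrame(callRate = cr, lrrSd = noise, gcWaveFactor = wavePre,
            gcWaveFactorCorrected = wavePost,
            cnvCount = as.integer(cnvCount),
            pihatMax = maxPartner,
            PC1 = pca$coords[, 1], PC2 = pca$coords[, 2],
            passCallRate = passCR, passLrrSd = passNoise,
            passGcWave = passWave, passDuplicate = passDup,
            passPca = passPca, passCnvCount = as.logical(passCnv),
            excluded = !apply(pass, 1L, all), reasons = reasons,
            row.names = colnames(x))
}
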