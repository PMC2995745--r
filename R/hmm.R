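## Six-state distance-aware HMM over ordered probes emitting (LRR, BAF).
## States: CN0, CN1, CN2, CN2-LOH, CN3, CN4.  The CN2-LOH state explains
## long runs of homozygosity without forcing a false deletion call.

#' Construct a copy-number HMM
#'
#' @param lrrMean,lrrSd per-state LRR emission mean/SD (order CN0, CN1,
#'   CN2, CN2-LOH, CN3, CN4).
#' @param bafSd SD of the interior BAF genotype bands.
#' @param transBase 6x6 row-stochastic base transition matrix (the
#'   large-distance limit).
#' @param distScale transition distance scale D in bp.
#' @param outlierFrac uniform outlier mass mixed into every emission.
#' @return A [CnvHmm].
#' @export
cnvHmm <- function(lrrMean = c(-3.5, -0.66, 0, 0, 0.40, 0.68),
                   lrrSd = c(1.3, 0.28, 0.16, 0.16, 0.21, 0.24),
                   bafSd = 0.04, transBase = NULL, distScale = 1e5,
                   outlierFrac = 0.01) {
  if (is.null(transBase)) {
    off <- matrix(1e-5, 6, 6)
    off[3, ] <- c(1e-5, 1e-4, 0, 1e-4, 1e-4, 1e-5)     # from CN2
    off[c(1, 2, 4, 5, 6), 3] <- 0.01                   # CNV states -> CN2
    off[2, 1] <- 1e-4                                  # CN1 -> CN0
    off[5, 6] <- 1e-4; off[6, 5] <- 1e-4               # CN3 <-> CN4
    diag(off) <- 0
    transBase <- off
    diag(transBase) <- 1 - rowSums(off)
  }
  dimnames(transBase) <- list(HMM_STATES, HMM_STATES)
  new("CnvHmm", states = HMM_STATES, lrrMean = as.numeric(lrrMean),
      lrrSd = as.numeric(lrrSd), bafSd = as.numeric(bafSd),
      transBase = transBase, distScale = as.numeric(distScale),
      outlierFrac = as.numeric(outlierFrac))
}

#' @rdname cnvHmm
#' @export
cnvHmmDefaults <- function() cnvHmm()

## near-diploid initial state distribution
.hmmInit <- function() {
  pi0 <- c(1e-4, 1e-3, 0.9969, 1e-3, 1e-3, 1e-4)
  pi0 / sum(pi0)
}

## BAF genotype bands and weights for one state given PFB p.
.bafBands <- function(state, p) {
  q <- 1 - p
  switch(state,
         list(bands = 0.5, weights = 1),                       # CN0: uniform
         list(bands = c(0, 1), weights = c(q, p)),             # CN1
         list(bands = c(0, 0.5, 1),
              weights = c(q^2, 2 * p * q, p^2)),               # CN2
         list(bands = c(0, 1), weights = c(q, p)),             # CN2-LOH
         list(bands = c(0, 1/3, 2/3, 1),
              weights = c(q^3, 3 * p * q^2, 3 * p^2 * q, p^3)),# CN3
         list(bands = c(0, 0.25, 0.5, 0.75, 1),
              weights = c(q^4, 4 * p * q^3, 6 * p^2 * q^2,
                          4 * p^3 * q, p^4)))                  # CN4
}

## Vectorized BAF band-mixture density for one state; baf is a vector or
## probes-x-samples matrix, p recycles along probes.  Boundary bands (0, 1)
## are half-Gaussians carrying the reflected mass.
.bafStateDensity <- function(baf, p, state, bafSd) {
  if (state == 1L) {
    d <- baf; d[] <- 1                                 # CN0: uniform on [0,1]
    return(d)
  }
  q <- 1 - p
  bandW <- switch(state,
                  NULL,
                  list(`0` = q, `1` = p),
                  list(`0` = q^2, `0.5` = 2 * p * q, `1` = p^2),
                  list(`0` = q, `1` = p),
                  list(`0` = q^3, `0.333333333333333` = 3 * p * q^2,
                       `0.666666666666667` = 3 * p^2 * q, `1` = p^3),
                  list(`0` = q^4, `0.25` = 4 * p * q^3,
                       `0.5` = 6 * p^2 * q^2, `0.75` = 4 * p^3 * q,
                       `1` = p^4))
  d <- baf; d[] <- 0
  for (nm in names(bandW)) {
    b <- as.numeric(nm)
    half <- if (b %in% c(0, 1)) 2 else 1
    d <- d + bandW[[nm]] * half * dnorm(baf, b, bafSd)
  }
  d
}

#' Emission log-density of the copy-number HMM
#'
#' LRR and BAF are treated as conditionally independent given the state.
#' The LRR term is Gaussian per state; the BAF term is a genotype-band
#' mixture weighted by the population B-allele frequency (CN0 is uniform;
#' boundary bands at 0/1 are half-Gaussians).  Every term is mixed with a
#' small uniform outlier component, and masked (`NA`) values drop their
#' term, so probes without a usable BAF contribute LRR-only evidence.
#'
#' @param model a [CnvHmm].
#' @param lrr,baf values — vectors of length T, or probes-x-samples
#'   matrices.
#' @param pfb population B-allele frequency, recycled along probes and
#'   clamped to \[0.01, 0.99\].
#' @param state optional state name or index; when omitted, all six.
#' @return For vector input: a T x 6 matrix (or vector for one state).
#'   For matrix input: a list of six matrices (or one matrix).
#' @export
emissionLogProb <- function(model, lrr, baf, pfb, state = NULL) {
  stopifnot(is(model, "CnvHmm"))
  p <- pmin(0.99, pmax(0.01, pfb))
  eps <- model@outlierFrac
  vecIn <- is.null(dim(lrr))
  states <- if (is.null(state)) 1:6 else {
    if (is.character(state)) match(state, model@states) else as.integer(state)
  }
  one <- function(s) {
    dl <- dnorm(lrr, model@lrrMean[s], model@lrrSd[s])
    dl <- (1 - eps) * dl + eps * 0.1          # uniform over an LRR width of 10
    dl[is.na(lrr)] <- 1
    db <- .bafStateDensity(baf, p, s, model@bafSd)
    db <- (1 - eps) * db + eps
    db[is.na(baf)] <- 1
    log(dl) + log(db)
  }
  out <- lapply(states, one)
  if (length(out) == 1L) return(out[[1L]])
  if (vecIn) do.call(cbind, setNames(out, model@states[states]))
  else setNames(out, model@states[states])
}

#' Distance-dependent transition matrix
#'
#' Off-diagonal entries of the base matrix are scaled by
#' `f(d) = 1 - 0.9 * exp(-d / D)` and the diagonal restores row sums to 1,
#' so short inter-probe gaps favour extending the current state and the
#' base matrix is recovered in the large-distance limit.
#'
#' @param d inter-probe distance in bp (clamped below at 1).
#' @param model a [CnvHmm].
#' @return A 6x6 row-stochastic matrix.
#' @export
transitionMatrix <- function(d, model) {
  f <- 1 - 0.9 * exp(-max(d, 1) / model@distScale)
  off <- model@transBase
  diag(off) <- 0
  off <- off * f
  diag(off) <- 1 - rowSums(off)
  off
}

## Log transition cube for a probe ladder (S x S x (T-1)) plus the f(d)
## vector used by the training M-step.
.transCube <- function(positions, model) {
  d <- pmax(diff(positions), 1)
  f <- 1 - 0.9 * exp(-d / model@distScale)
  off <- model@transBase
  diag(off) <- 0
  rs <- rowSums(off)
  cube <- array(0, c(6, 6, length(d)))
  for (i in 1:6) for (j in 1:6) {
    cube[i, j, ] <- if (i == j) log(1 - rs[i] * f) else
      log(pmax(off[i, j], 1e-12) * f)
  }
  list(cube = cube, f = f)
}

.pathLogProb <- function(path, logem, cube, logpi) {
  T <- length(path)
  lp <- logpi[path[1]] + logem[1, path[1]]
  if (T > 1L) {
    t <- seq_len(T - 1L)
    lp <- lp + sum(cube[cbind(path[t], path[t + 1L], t)]) +
      sum(logem[cbind(2:T, path[-1L])])
  }
  lp
}

#' Viterbi copy-number segmentation
#'
#' Decodes the maximum a posteriori state path per sample and chromosome
#' and converts maximal runs of non-diploid states into calls with
#' 1-based inclusive boundaries at the first/last probe of the run.  The
#' confidence is the log10 likelihood ratio of the decoded path against
#' the same path with the segment forced to the diploid state.
#'
#' @param x a [SnpSignalSet] with `baf` and `lrr` assays, or a list with
#'   `lrr`, `baf` matrices and a `manifest`.
#' @param pfb per-probe population B-allele frequency.
#' @param model a [CnvHmm].
#' @param samples columns to decode (default: all).
#' @return A [CnvCalls] object.
#' @export
callCnvs <- function(x, pfb, model = cnvHmmDefaults(), samples = NULL) {
  if (is(x, "SnpSignalSet")) {
    lrr <- assay(x, "lrr"); baf <- assay(x, "baf"); man <- snpManifest(x)
  } else {
    lrr <- x$lrr; baf <- x$baf; man <- x$manifest
  }
  samples <- samples %||% colnames(lrr)
  chrs <- unique(as.character(seqnames(man)))
  logpi <- log(.hmmInit())
  out <- list()
  for (chr in chrs) {
    idx <- which(as.character(seqnames(man)) == chr)
    if (length(idx) < 2L) next
    pos <- start(man)[idx]
    names <- mcols(man)$Name[idx]
    tc <- .transCube(pos, model)
    em <- emissionLogProb(model, lrr[idx, samples, drop = FALSE],
                          baf[idx, samples, drop = FALSE], pfb[idx])
    for (sj in seq_along(samples)) {
      logem <- vapply(em, function(e) e[, sj], numeric(length(idx)))
      path <- .viterbi_cpp(logem, tc$cube, logpi)
      runs <- rle(path)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values != 3L)) {
        i1 <- starts[k]; i2 <- ends[k]
        forced <- path
        forced[i1:i2] <- 3L
        conf <- (.pathLogProb(path, logem, tc$cube, logpi) -
                 .pathLogProb(forced, logem, tc$cube, logpi)) / log(10)
        st <- runs$values[k]
        out[[length(out) + 1L]] <- GRanges(
          chr, IRanges(pos[i1], pos[i2]),
          sample = samples[sj], state = HMM_STATES[st],
          cn = unname(HMM_COPYNUMBER[st]), numsnp = i2 - i1 + 1L,
          startSnp = names[i1], endSnp = names[i2], conf = conf)
      }
    }
  }
  calls <- if (length(out)) do.call(c, out) else
    GRanges(sample = character(), state = character(), cn = integer(),
            numsnp = integer(), startSnp = character(),
            endSnp = character(), conf = numeric())
  new("CnvCalls", calls)
}

#' Baum-Welch training in successive sample batches
#'
#' Re-estimates the LRR emission SDs (all states), the LRR means of the
#' non-diploid states (order constraint enforced by projection) and the
#' base transition matrix, in three successive batches of `batchSize`
#' samples: batch 1 uses the lowest-noise samples (smallest LRR SD), later
#' batches draw randomly without replacement, and each batch warm-starts
#' from the previous estimate.  Expected transition counts are
#' inverse-weighted by the distance factor f(d) to recover base rates
#' (approximate M-step; the likelihood is monitored and a decrease beyond
#' tolerance aborts with diagnostics).
#'
#' @param x a [SnpSignalSet] with `lrr`/`baf` assays, or a list with
#'   `lrr`, `baf`, `manifest`.
#' @param pfb per-probe population B-allele frequency.
#' @param model starting [CnvHmm].
#' @param nBatches,batchSize training schedule (default 3 x 30).
#' @param maxIter EM iterations per batch.
#' @param seed seed for the random batch draws.
#' @return The trained [CnvHmm], with a `loglik` attribute tracing batch
#'   likelihoods.
#' @export
trainHmm <- function(x, pfb, model = cnvHmmDefaults(), nBatches = 3L,
                     batchSize = 30L, maxIter = 10L, seed = 1L) {
  if (is(x, "SnpSignalSet")) {
    lrr <- assay(x, "lrr"); baf <- assay(x, "baf"); man <- snpManifest(x)
  } else {
    lrr <- x$lrr; baf <- x$baf; man <- x$manifest
  }
  n <- ncol(lrr)
  if (n < batchSize) stop("training needs at least ", batchSize, " samples")
  pos <- start(man)
  noise <- lrrSd(lrr)
  ord <- order(noise)
  batches <- list(ord[seq_len(batchSize)])
  pool <- setdiff(seq_len(n), batches[[1L]])
  withSeed(seed, {
    for (b in seq_len(nBatches - 1L)) {
      if (length(pool) >= batchSize) {
        pick <- sample(pool, batchSize)
        pool <- setdiff(pool, pick)
      } else {
        pick <- sample(seq_len(n), batchSize)
      }
      batches[[b + 1L]] <- pick
    }
  })
  logpi <- log(.hmmInit())
  trace <- list()
  for (b in seq_along(batches)) {
    cols <- batches[[b]]
    lls <- numeric()
    for (iter in seq_len(maxIter)) {
      tc <- .transCube(pos, model)
      em <- emissionLogProb(model, lrr[, cols, drop = FALSE],
                            baf[, cols, drop = FALSE], pfb)
      occ <- matrix(0, 1, 6)
      sumX <- sumX2 <- rep(0, 6)
      occT <- rep(0, 6)                 # occupancy over transition origins
      xiW <- matrix(0, 6, 6)
      ll <- 0
      for (j in seq_along(cols)) {
        logem <- vapply(em, function(e) e[, j], numeric(nrow(lrr)))
        fb <- .forward_backward_cpp(logem, tc$cube, logpi, 1 / tc$f)
        ll <- ll + fb$loglik
        g <- fb$gamma
        v <- lrr[, cols[j]]
        okL <- is.finite(v)
        occ <- occ + colSums(g)
        sumX <- sumX + colSums(g[okL, , drop = FALSE] * v[okL])
        sumX2 <- sumX2 + colSums(g[okL, , drop = FALSE] * v[okL]^2)
        occT <- occT + colSums(g[-nrow(g), , drop = FALSE])
        xiW <- xiW + fb$xiWeighted
      }
      if (length(lls) && ll < tail(lls, 1) - (1e-3 * abs(tail(lls, 1)) + 1))
        stop(sprintf("training likelihood decreased (batch %d iter %d: %.2f -> %.2f)",
                     b, iter, tail(lls, 1), ll))
      lls <- c(lls, ll)
      model <- .hmmMStep(model, occ[1, ], sumX, sumX2, occT, xiW)
      if (length(lls) > 1L &&
          abs(diff(tail(lls, 2))) < 1e-4 * (abs(ll) + 1)) break
    }
    trace[[b]] <- lls
  }
  attr(model, "loglik") <- trace
  model
}

.hmmMStep <- function(model, occ, sumX, sumX2, occT, xiW) {
  mu <- model@lrrMean
  sdv <- model@lrrSd
  upd <- occ > 1e-6
  muNew <- ifelse(upd, sumX / pmax(occ, 1e-12), mu)
  ## diploid means stay pinned at 0; enforce state ordering by projection
  muNew[3] <- 0; muNew[4] <- 0
  muNew[5] <- max(muNew[5], 0.05)
  muNew[6] <- max(muNew[6], muNew[5] + 0.05)
  muNew[2] <- min(muNew[2], -0.05)
  muNew[1] <- min(muNew[1], muNew[2] - 0.1)
  varNew <- sumX2 / pmax(occ, 1e-12) - (sumX / pmax(occ, 1e-12))^2
  sdNew <- ifelse(upd, pmax(sqrt(pmax(varNew, 0)), 0.05), sdv)
  off <- xiW
  off <- off / pmax(occT, 1e-12)
  off <- pmax(off, 1e-8)
  diag(off) <- 0
  ## keep the chain strongly diagonal: cap total leave probability
  rs <- rowSums(off)
  over <- rs > 0.2
  off[over, ] <- off[over, ] * (0.2 / rs[over])
  tb <- off
  diag(tb) <- 1 - rowSums(off)
  dimnames(tb) <- dimnames(model@transBase)
  cnvHmm(lrrMean = muNew, lrrSd = sdNew, bafSd = model@bafSd,
         transBase = tb, distScale = model@distScale,
         outlierFrac = model@outlierFrac)
}
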