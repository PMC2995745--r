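## Raw X/Y -> polar (theta, R) -> canonical genotype clusters -> BAF/LRR.

#' Polar transform of raw two-channel intensities
#'
#' Raw intensities are floored at 1 and reduced with log10; then
#' `theta = (2/pi) * atan2(log10(Y), log10(X))` and `R = log10(X) + log10(Y)`
#' (the "A+B" total on the log scale).  Non-finite inputs yield masked
#' (`NA`) probes rather than errors.
#'
#' @param X,Y raw channel intensities (vectors or matrices of equal shape).
#' @return `list(theta =, R =)` with the same shape as the input.
#' @export
#' @examples
#' toPolar(1000, 1000)  # theta 0.5, R 6
toPolar <- function(X, Y) {
  bad <- !is.finite(X) | !is.finite(Y)
  x <- log10(pmax(X, 1))
  y <- log10(pmax(Y, 1))
  theta <- (2 / pi) * atan2(y, x)
  R <- x + y
  theta[bad] <- NA_real_
  R[bad] <- NA_real_
  list(theta = theta, R = R)
}

#' @describeIn toPolar apply the polar transform to the `X`/`Y` assays of a
#'   [SnpSignalSet], adding/replacing its `theta` and `R` assays.
#' @param x a `SnpSignalSet` with `X` and `Y` assays.
#' @export
polarize <- function(x) {
  p <- toPolar(assay(x, "X"), assay(x, "Y"))
  assay(x, "theta") <- p$theta
  assay(x, "R") <- p$R
  x
}

#' Build canonical AA/AB/BB genotype clusters
#'
#' For every SNP the AA, AB and BB cluster centers in (theta, R) are the
#' 10%-trimmed means over samples carrying that genotype call (calls with
#' confidence above `maxConfidence` are ignored).  A missing AB cluster is
#' imputed at the homozygote theta midpoint with `R = max(R_AA, R_BB)`; a
#' missing homozygote (with the other two observed) is imputed by
#' reflecting the observed spacing.  SNPs with fewer than two observed
#' clusters, or whose (possibly imputed) centers are not strictly ordered
#' in theta, are flagged unusable.
#'
#' @param x a [SnpSignalSet] with `theta`, `R`, `genotype`, `genoConf`
#'   assays, or a list with those elements as matrices.
#' @param minMembers minimum confident calls for a cluster to count as
#'   observed.
#' @param maxConfidence calls with confidence strictly above this are
#'   ignored (smaller confidence = better call).
#' @return A [GenotypeClusters] object.
#' @export
buildClusters <- function(x, minMembers = 2L, maxConfidence = 0.1) {
  theta <- if (is(x, "SnpSignalSet")) assay(x, "theta") else x$theta
  R <- if (is(x, "SnpSignalSet")) assay(x, "R") else x$R
  geno <- if (is(x, "SnpSignalSet")) assay(x, "genotype") else x$genotype
  conf <- if (is(x, "SnpSignalSet")) assay(x, "genoConf") else x$genoConf
  if (is.null(conf)) conf <- matrix(0, nrow(theta), ncol(theta))
  if (ncol(theta) == 0L) stop("no samples to cluster")
  m <- nrow(theta)
  snp <- rownames(theta) %||% sprintf("snp%06d", seq_len(m))

  use <- !is.na(geno) & !is.na(conf) & conf <= maxConfidence &
    is.finite(theta) & is.finite(R)
  thC <- RC <- matrix(NA_real_, m, 3, dimnames = list(snp, GENOTYPE_LEVELS))
  counts <- matrix(0L, m, 3, dimnames = list(snp, GENOTYPE_LEVELS))
  for (g in 0:2) {
    sel <- use & geno == g
    counts[, g + 1L] <- rowSums(sel)
    idx <- which(counts[, g + 1L] >= minMembers)
    if (length(idx)) {
      thC[idx, g + 1L] <- vapply(idx, function(i)
        mean(theta[i, sel[i, ]], trim = 0.1), numeric(1))
      RC[idx, g + 1L] <- vapply(idx, function(i)
        mean(R[i, sel[i, ]], trim = 0.1), numeric(1))
    }
  }

  observed <- !is.na(thC)
  nObs <- rowSums(observed)
  imputed <- matrix(FALSE, m, 3, dimnames = list(snp, GENOTYPE_LEVELS))

  ## impute the single missing component where two are observed
  fix <- which(nObs == 2L)
  for (i in fix) {
    miss <- which(!observed[i, ])
    if (miss == 2L) {                      # AB from both homozygotes
      thC[i, 2] <- (thC[i, 1] + thC[i, 3]) / 2
      RC[i, 2] <- max(RC[i, 1], RC[i, 3])
    } else if (miss == 3L) {               # BB by reflecting AA->AB spacing
      thC[i, 3] <- thC[i, 2] + (thC[i, 2] - thC[i, 1])
      RC[i, 3] <- RC[i, 2]
    } else {                               # AA by reflecting AB->BB spacing
      thC[i, 1] <- thC[i, 2] - (thC[i, 3] - thC[i, 2])
      RC[i, 1] <- RC[i, 2]
    }
    imputed[i, miss] <- TRUE
  }

  ordered <- !is.na(thC[, 1]) & !is.na(thC[, 2]) & !is.na(thC[, 3]) &
    thC[, 1] < thC[, 2] & thC[, 2] < thC[, 3] &
    thC[, 1] >= 0 & thC[, 3] <= 1
  posR <- !is.na(RC[, 1]) & !is.na(RC[, 2]) & !is.na(RC[, 3]) &
    RC[, 1] > 0 & RC[, 2] > 0 & RC[, 3] > 0
  usable <- nObs >= 2L & ordered & posR
  thC[!usable, ] <- NA_real_
  RC[!usable, ] <- NA_real_
  new("GenotypeClusters", snp = snp, theta = thC, R = RC, counts = counts,
      usable = usable, imputed = imputed)
}

#' Derive B allele frequency from theta
#'
#' Piecewise-linear interpolation against the canonical cluster centers:
#' theta at or below the AA center maps to 0, at the AB center to 0.5, at
#' or above the BB center to 1, linear in between.  Unusable SNPs are
#' masked.
#'
#' @param theta matrix (probes x samples) or vector of theta values.
#' @param clusters a [GenotypeClusters] aligned to the rows of `theta`.
#' @return BAF values with the shape of `theta` (`NA` where masked).
#' @export
deriveBAF <- function(theta, clusters) {
  thA <- clusters@theta[, 1]; thH <- clusters@theta[, 2]
  thB <- clusters@theta[, 3]
  lo <- 0.5 * (theta - thA) / (thH - thA)
  hi <- 0.5 + 0.5 * (theta - thH) / (thB - thH)
  baf <- ifelse(theta <= thH, lo, hi)
  baf <- pmin(1, pmax(0, baf))
  baf[!clusters@usable | !is.finite(theta)] <- NA_real_
  dim(baf) <- dim(theta)
  dimnames(baf) <- dimnames(theta)
  baf
}

#' Derive log R ratio from observed polar R
#'
#' The expected R at the observed theta is the piecewise-linear
#' interpolation of the three cluster (theta, R) anchor points, clamped
#' beyond the end clusters; `LRR = log2(R_obs / R_exp)`.  Probes with a
#' non-positive expected R or unusable clusters are masked.
#'
#' @param theta,Robs matrices (probes x samples) or vectors.
#' @param clusters a [GenotypeClusters] aligned to the rows.
#' @return LRR values with the shape of the input.
#' @export
deriveLRR <- function(theta, Robs, clusters) {
  thA <- clusters@theta[, 1]; thH <- clusters@theta[, 2]
  thB <- clusters@theta[, 3]
  RA <- clusters@R[, 1]; RH <- clusters@R[, 2]; RB <- clusters@R[, 3]
  wLo <- (theta - thA) / (thH - thA)
  wHi <- (theta - thH) / (thB - thH)
  Rexp <- ifelse(theta <= thA, RA,
          ifelse(theta <= thH, RA + wLo * (RH - RA),
          ifelse(theta <= thB, RH + wHi * (RB - RH), RB)))
  lrr <- log2(Robs / Rexp)
  lrr[!clusters@usable | !is.finite(theta) | !is.finite(Robs) |
        is.na(Rexp) | Rexp <= 0 | Robs <= 0] <- NA_real_
  dim(lrr) <- dim(Robs)
  dimnames(lrr) <- dimnames(Robs)
  lrr
}

#' @describeIn deriveBAF add `baf` and `lrr` assays to a [SnpSignalSet].
#' @param x a `SnpSignalSet` with `theta` and `R` assays.
#' @export
deriveSignal <- function(x, clusters) {
  assay(x, "baf") <- deriveBAF(assay(x, "theta"), clusters)
  assay(x, "lrr") <- deriveLRR(assay(x, "theta"), assay(x, "R"), clusters)
  x
}

#' Quantile-normalized Log2Ratio of total intensities
#'
#' The contrasting intensity summary that bypasses genotype clusters:
#' per-sample total (X+Y) distributions are quantile-normalized to the mean
#' quantile profile (via [limma::normalizeQuantiles]), and
#' `Log2Ratio = log2(normalized total / per-SNP median across samples)`.
#'
#' @param totals matrix (probes x samples) of raw totals `X + Y`.
#' @return Matrix of Log2Ratio values, same shape.
#' @export
log2RatioQuantile <- function(totals) {
  if (ncol(totals) < 2L)
    stop("Log2Ratio needs at least 2 samples (median reference undefined)")
  nt <- limma::normalizeQuantiles(totals)
  med <- apply(nt, 1L, median)
  log2(nt / med)
}

#' Population B allele frequency table
#'
#' Mean BAF per SNP across (QC-passing) samples, clipped to \[0.01, 0.99\].
#'
#' @param baf matrix (probes x samples) of BAF values.
#' @param usable optional logical mask of usable SNPs (rows); masked rows
#'   get `NA`.
#' @return Numeric vector of PFB values per probe.
#' @export
computePFB <- function(baf, usable = NULL) {
  if (ncol(baf) < 1L) stop("PFB needs at least one sample")
  pfb <- rowMeans(baf, na.rm = TRUE)
  pfb <- pmin(0.99, pmax(0.01, pfb))
  pfb[is.nan(pfb)] <- NA_real_
  if (!is.null(usable)) pfb[!usable] <- NA_real_
  pfb
}

#' Fallback genotype caller (1-D Gaussian mixture on theta)
#'
#' Per SNP, a three-component Gaussian mixture on theta is fit by EM with
#' means initialized at 0.15/0.5/0.85 (components kept ordered); the call
#' is the maximum-posterior component, confidence is `1 - max posterior`,
#' and calls with confidence above 0.1 become no-calls.  Intended for
#' synthetic or standalone runs when no external caller output exists.
#'
#' @param theta matrix (probes x samples) of theta values.
#' @param maxIter EM iteration cap per SNP (SNPs that fail to converge are
#'   flagged unusable).
#' @param tol relative log-likelihood convergence tolerance.
#' @return `list(genotype =, conf =, converged =)`: integer B-allele copy
#'   matrix (`NA` = no-call), confidence matrix, and a per-SNP logical.
#' @export
callGenotypes <- function(theta, maxIter = 200L, tol = 1e-6) {
  m <- nrow(theta); n <- ncol(theta)
  if (n < 10L) stop("genotype calling needs >= 10 samples per SNP")
  geno <- matrix(NA_integer_, m, n, dimnames = dimnames(theta))
  conf <- matrix(NA_real_, m, n, dimnames = dimnames(theta))
  converged <- logical(m)
  for (i in seq_len(m)) {
    th <- theta[i, ]
    ok <- is.finite(th)
    fit <- .emMixture3(th[ok], maxIter = maxIter, tol = tol)
    converged[i] <- fit$converged
    if (!fit$converged) next
    g <- max.col(fit$post) - 1L
    best <- fit$post[cbind(seq_len(nrow(fit$post)), g + 1L)]
    cf <- 1 - best
    g[cf > 0.1] <- NA_integer_
    geno[i, ok] <- g
    conf[i, ok] <- cf
  }
  list(genotype = geno, conf = conf, converged = converged)
}

.emMixture3 <- function(th, maxIter = 200L, tol = 1e-6) {
  mu <- c(0.15, 0.5, 0.85)
  sig <- rep(0.05, 3)
  w <- rep(1 / 3, 3)
  n <- length(th)
  if (n == 0L) return(list(converged = FALSE))
  llOld <- -Inf
  converged <- FALSE
  post <- NULL
  for (it in seq_len(maxIter)) {
    d <- vapply(1:3, function(k) w[k] * dnorm(th, mu[k], sig[k]),
                numeric(n))
    tot <- rowSums(d)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    post <- d / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - llOld) <= tol * (abs(llOld) + 1)) {
      converged <- TRUE
      break
    }
    llOld <- ll
    nk <- colSums(post)
    upd <- nk > 1e-8
    mu[upd] <- (colSums(post * th) / nk)[upd]
    v <- vapply(1:3, function(k)
      sum(post[, k] * (th - mu[k])^2) / max(nk[k], 1e-8), numeric(1))
    sig[upd] <- pmax(sqrt(v[upd]), 5e-3)
    w <- nk / n
    ord <- order(mu)              # keep components ordered AA < AB < BB
    mu <- mu[ord]; sig <- sig[ord]; w <- w[ord];
  }
  if (!converged) return(list(converged = FALSE))
  d <- vapply(1:3, function(k) w[k] * dnorm(th, mu[k], sig[k]), numeric(n))
  tot <- rowSums(d); tot[tot <= 0] <- .Machine$double.xmin
  list(converged = TRUE, post = d / tot, mu = mu, sigma = sig, weight = w)
}
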