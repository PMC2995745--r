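## Synthetic two-channel SNP-array cohorts with known embedded CNVs.
##
## The generator works backwards from the polar representation the pipeline
## recovers: each probe's target theta is set by piecewise-linear
## interpolation of the configured AA/AB/BB cluster centers at the allelic
## fraction b/(a+b), and the target polar R (sum of log10 channel
## intensities) is a compressed function of total allele copies,
## R = (Rdip * (a+b+0.1)/2.1)^gamma with Rdip = 2*log10(intensityScale).
## The exponent gamma models PCR saturation: copy-number intensity
## differences shrink while the allelic (theta/BAF) signal stays intact.
## Raw X/Y are then emitted as 10^x, 10^y with correlated lognormal channel
## noise and a per-sample GC wave on the total log intensity.

#' CnvSpec: one embedded copy-number variant
#'
#' @slot chromosome chromosome name.
#' @slot start,end 1-based inclusive interval, `start < end`.
#' @slot copyNumber integer in \{0, 1, 3, 4\}.
#' @slot carrierGroup `"case"` or `"control"`.
#' @slot nCarriers number of carriers drawn (without replacement) from the
#'   carrier group.
#' @export
setClass("CnvSpec",
         representation(chromosome = "character", start = "numeric",
                        end = "numeric", copyNumber = "integer",
                        carrierGroup = "character", nCarriers = "integer"))

#' @rdname CnvSpec-class
#' @param chromosome,start,end,copyNumber,carrierGroup,nCarriers see slots.
#' @export
cnvSpec <- function(chromosome = "chr5", start, end, copyNumber = 3L,
                    carrierGroup = c("case", "control"), nCarriers = 5L) {
  new("CnvSpec", chromosome = chromosome, start = as.numeric(start),
      end = as.numeric(end), copyNumber = as.integer(copyNumber),
      carrierGroup = match.arg(carrierGroup),
      nCarriers = as.integer(nCarriers))
}

setValidity("CnvSpec", function(object) {
  msg <- character()
  if (object@start >= object@end) msg <- c(msg, "start must be < end")
  if (!object@copyNumber %in% c(0L, 1L, 3L, 4L))
    msg <- c(msg, "copyNumber must be one of 0, 1, 3, 4")
  if (!object@carrierGroup %in% c("case", "control"))
    msg <- c(msg, "carrierGroup must be 'case' or 'control'")
  if (object@nCarriers < 1L) msg <- c(msg, "nCarriers must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: study conditions for a synthetic cohort
#'
#' Defaults reproduce the reference study conditions: 1,693 cases and 4,506
#' controls over a ~2,000-probe, 3 Mb chromosome-5-like region, with channel
#' noise calibrated to a per-sample LRR SD near 0.2 and a PCR-saturation
#' exponent of 0.7.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param nCases,nControls cohort sizes.
#' @param nProbes number of probes on the simulated chromosome segment.
#' @param chromLength segment length in bp.
#' @param chrom chromosome name.
#' @param alleleFreqPrior two positive Beta shape parameters for the
#'   per-SNP B-allele frequency.
#' @param clusterThetaCenters canonical AA/AB/BB theta centers, strictly
#'   increasing in (0, 1).
#' @param intensityScale linear intensity per allele copy (raw units).
#' @param noiseSdLog SD of additive noise on each channel's log10 intensity.
#' @param channelCorr correlation of the two channels' log-intensity noise
#'   (shared hybridization/PCR efficiency); high correlation makes LRR much
#'   noisier than BAF, as on real arrays.
#' @param saturationGamma exponent in (0, 1\] compressing the summed
#'   log-scale intensity (PCR saturation); 1 = no compression.
#' @param waveAmplitudeSd SD of the per-sample GC-wave coefficient applied
#'   to centered GC on the log10 total-intensity scale.
#' @param embeddedCnvs list of [CnvSpec] objects.
#' @param nDuplicatePairs,nParentOffspringPairs related sample pairs to
#'   inject (duplicates share genotypes; parent-offspring share one allele
#'   per probe).
#' @param stratification `NULL`, or `list(fst =, fraction =)` describing two
#'   subpopulations with Balding-Nichols allele-frequency divergence.
#' @param callConfSd theta SD assumed by the generator's built-in genotype
#'   labeller when assigning calls and confidences.
#' @return A `SimulationConfig` object.
#' @export
simulationConfig <- function(seed = 1L, nCases = 100L, nControls = 100L,
                             nProbes = 2000L, chromLength = 3e6,
                             chrom = "chr5",
                             alleleFreqPrior = c(1, 1),
                             clusterThetaCenters = c(0.1, 0.5, 0.9),
                             intensityScale = 1000,
                             noiseSdLog = 0.26, channelCorr = 0.9,
                             saturationGamma = 0.7, waveAmplitudeSd = 0.05,
                             embeddedCnvs = list(),
                             nDuplicatePairs = 0L,
                             nParentOffspringPairs = 0L,
                             stratification = NULL,
                             callConfSd = 0.05) {
  new("SimulationConfig", seed = as.integer(seed),
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      nProbes = as.integer(nProbes), chromLength = as.numeric(chromLength),
      chrom = chrom, alleleFreqPrior = as.numeric(alleleFreqPrior),
      clusterThetaCenters = as.numeric(clusterThetaCenters),
      intensityScale = as.numeric(intensityScale),
      noiseSdLog = as.numeric(noiseSdLog),
      channelCorr = as.numeric(channelCorr),
      saturationGamma = as.numeric(saturationGamma),
      waveAmplitudeSd = as.numeric(waveAmplitudeSd),
      embeddedCnvs = embeddedCnvs,
      nDuplicatePairs = as.integer(nDuplicatePairs),
      nParentOffspringPairs = as.integer(nParentOffspringPairs),
      stratification = stratification %||% list(),
      callConfSd = as.numeric(callConfSd))
}

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig",
         representation(seed = "integer", nCases = "integer",
                        nControls = "integer", nProbes = "integer",
                        chromLength = "numeric", chrom = "character",
                        alleleFreqPrior = "numeric",
                        clusterThetaCenters = "numeric",
                        intensityScale = "numeric", noiseSdLog = "numeric",
                        channelCorr = "numeric", saturationGamma = "numeric",
                        waveAmplitudeSd = "numeric", embeddedCnvs = "list",
                        nDuplicatePairs = "integer",
                        nParentOffspringPairs = "integer",
                        stratification = "list", callConfSd = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  ctc <- object@clusterThetaCenters
  if (length(ctc) != 3L || !(0 < ctc[1] && ctc[1] < ctc[2] &&
                             ctc[2] < ctc[3] && ctc[3] < 1))
    msg <- c(msg, "cluster theta centers must satisfy 0 < AA < AB < BB < 1")
  if (object@nProbes < 2L) msg <- c(msg, "nProbes must be >= 2")
  if (object@saturationGamma <= 0 || object@saturationGamma > 1)
    msg <- c(msg, "saturationGamma must lie in (0, 1]")
  if (any(object@alleleFreqPrior <= 0))
    msg <- c(msg, "alleleFreqPrior shapes must be positive")
  if (object@noiseSdLog < 0) msg <- c(msg, "noiseSdLog must be >= 0")
  if (object@waveAmplitudeSd < 0)
    msg <- c(msg, "waveAmplitudeSd must be >= 0")
  if (object@channelCorr < 0 || object@channelCorr > 1)
    msg <- c(msg, "channelCorr must lie in [0, 1]")
  if (object@intensityScale <= 1)
    msg <- c(msg, "intensityScale must exceed 1")
  if (!all(vapply(object@embeddedCnvs, is, logical(1), "CnvSpec")))
    msg <- c(msg, "embeddedCnvs must be a list of CnvSpec")
  if (length(object@stratification) &&
      !all(c("fst", "fraction") %in% names(object@stratification)))
    msg <- c(msg, "stratification needs elements 'fst' and 'fraction'")
  if (length(msg)) msg else TRUE
})

#' The canonical default fixture
#'
#' 1,693 cases and 4,506 controls over ~2,000 probes spanning 3 Mb, with a
#' single 646,850 bp CN=3 duplication carried by 5 cases and no controls —
#' the configuration used throughout the package's end-to-end validation.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [simulationConfig()].
#' @return A [SimulationConfig].
#' @export
defaultFixtureConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, nCases = 1693L, nControls = 4506L,
               nProbes = 2000L, chromLength = 3e6,
               embeddedCnvs = list(cnvSpec(chromosome = "chr5",
                                           start = 1200001, end = 1846850,
                                           copyNumber = 3L,
                                           carrierGroup = "case",
                                           nCarriers = 5L)))
  override <- list(...)
  args[names(override)] <- override
  do.call(simulationConfig, args)
}

#' Simulate a probe manifest
#'
#' Draws strictly increasing probe positions uniformly over the segment, a
#' smooth local-GC track in \[0.2, 0.8\] (sum of long-period sinusoids with
#' seeded random phases) and per-SNP B-allele frequencies from the Beta
#' prior.
#'
#' @param config a [SimulationConfig].
#' @return A [SnpManifest] with `Name`, `GC` and `FreqB` columns.
#' @export
simulateManifest <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@nProbes < 2L) stop("configuration error: nProbes must be >= 2")
  withSeed(config@seed, {
    m <- config@nProbes
    pos <- sort(sample.int(config@chromLength, m))
    ph <- runif(3, 0, 2 * pi)
    x <- pos / config@chromLength
    gc <- 0.45 + 0.10 * sin(2 * pi * 3 * x + ph[1]) +
      0.06 * sin(2 * pi * 7 * x + ph[2]) +
      0.04 * sin(2 * pi * 13 * x + ph[3])
    gc <- pmin(0.8, pmax(0.2, gc))
    freqB <- rbeta(m, config@alleleFreqPrior[1], config@alleleFreqPrior[2])
    SnpManifest(names = sprintf("rs%06d", seq_len(m)), chrom = config@chrom,
                positions = pos, gc = gc, freqB = freqB)
  })
}

## theta target from allelic fraction f = b/(a+b), piecewise-linear through
## the configured cluster centers (f = 0, 0.5, 1 -> AA, AB, BB centers).
.thetaFromFraction <- function(f, centers) {
  lo <- centers[1] + (f / 0.5) * (centers[2] - centers[1])
  hi <- centers[2] + ((f - 0.5) / 0.5) * (centers[3] - centers[2])
  ifelse(f <= 0.5, lo, hi)
}

#' Inject duplicate and parent-offspring pairs into a genotype matrix
#'
#' Duplicate pairs copy the first member's genotypes to the second;
#' parent-offspring pairs rebuild the offspring's genotype from one allele
#' transmitted by the parent plus one population allele.  Pair members are
#' taken from `eligible` (both members replaced/overwritten in place).
#'
#' @param genotypes integer matrix (probes x samples) of B-allele copies.
#' @param freqB per-probe B-allele frequency used for the non-transmitted
#'   allele.
#' @param nDuplicatePairs,nParentOffspringPairs pair counts.
#' @param eligible candidate column indices (defaults to all columns).
#' @return `list(genotypes =, pairs =)` where `pairs` is a data.frame with
#'   columns `type`, `member1`, `member2` (column indices).
#' @export
injectRelatedness <- function(genotypes, freqB, nDuplicatePairs = 0L,
                              nParentOffspringPairs = 0L,
                              eligible = seq_len(ncol(genotypes))) {
  nd <- as.integer(nDuplicatePairs)
  np <- as.integer(nParentOffspringPairs)
  need <- 2L * (nd + np)
  if (need == 0L)
    return(list(genotypes = genotypes,
                pairs = data.frame(type = character(), member1 = integer(),
                                   member2 = integer())))
  if (need > length(eligible))
    stop("requested related pairs exceed available samples / 2")
  picked <- sample(eligible, need)
  pairs <- data.frame(
    type = rep(c("duplicate", "parent-offspring"), times = c(nd, np)),
    member1 = picked[seq_len(nd + np) * 2L - 1L],
    member2 = picked[seq_len(nd + np) * 2L])
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$member1[k]; j <- pairs$member2[k]
    if (pairs$type[k] == "duplicate") {
      genotypes[, j] <- genotypes[, i]
    } else {
      transmitted <- rbinom(nrow(genotypes), 1L, genotypes[, i] / 2)
      other <- rbinom(nrow(genotypes), 1L, freqB)
      genotypes[, j] <- transmitted + other
    }
  }
  list(genotypes = genotypes, pairs = pairs)
}

#' Simulate a raw-intensity cohort with truth tables
#'
#' Draws Hardy-Weinberg genotypes (optionally under two-subpopulation
#' Balding-Nichols divergence), injects related pairs, assigns embedded CNV
#' carriers and their extra/lost allele copies, and emits raw two-channel
#' intensities through the saturating polar intensity model described in
#' the package vignette.
#'
#' @param config a [SimulationConfig].
#' @param manifest the matching [SnpManifest] from [simulateManifest()].
#' @return A [SnpSignalSet] with assays `X`, `Y`, `theta`, `R`, `genotype`,
#'   `genoConf`; `colData` columns `label`, `subpop`, `waveCoef`,
#'   `relatedRole`; and `metadata(x)$truth` holding `intervals` (a `GRanges`
#'   of carrier intervals with `sample` and `copyNumber`), `genotypes` (the
#'   true diploid B-allele copies), `carrierCopies` (per-carrier per-probe
#'   allele copies inside CNVs), `pairs`, and the config.
#' @export
simulateCohort <- function(config, manifest) {
  stopifnot(is(config, "SimulationConfig"), is(manifest, "SnpManifest"))
  m <- length(manifest)
  pos <- start(manifest)
  for (spec in config@embeddedCnvs) {
    if (spec@start < min(pos) || spec@end > max(pos))
      stop("configuration error: embedded CNV interval outside manifest span")
  }
  withSeed(config@seed + 1L, {
    nCase <- config@nCases; nCtrl <- config@nControls; n <- nCase + nCtrl
    ids <- c(sprintf("case%04d", seq_len(nCase)),
             sprintf("ctrl%04d", seq_len(nCtrl)))
    label <- rep(c("case", "control"), c(nCase, nCtrl))
    freqB <- mcols(manifest)$FreqB
    if (is.null(freqB))
      stop("manifest lacks FreqB; use a manifest from simulateManifest()")

    ## subpopulation allele frequencies (Balding-Nichols)
    strat <- config@stratification
    if (length(strat)) {
      fst <- strat$fst
      p2 <- rbeta(m, freqB * (1 - fst) / fst, (1 - freqB) * (1 - fst) / fst)
      subpop <- 1L + (runif(n) < strat$fraction)
      pmat <- cbind(freqB, p2)
    } else {
      subpop <- rep(1L, n)
      pmat <- cbind(freqB)
    }

    ## diploid genotypes, HWE within subpopulation
    G <- matrix(0L, m, n)
    for (s in unique(subpop)) {
      cols <- which(subpop == s)
      G[, cols] <- matrix(rbinom(m * length(cols), 2L, pmat[, s]),
                          m, length(cols))
    }

    ## embedded CNV carriers, drawn before relatedness so truth carriers
    ## stay unrelated
    caseIdx <- which(label == "case"); ctrlIdx <- which(label == "control")
    carrierOf <- vector("list", length(config@embeddedCnvs))
    usedCarriers <- integer()
    for (k in seq_along(config@embeddedCnvs)) {
      spec <- config@embeddedCnvs[[k]]
      pool <- setdiff(if (spec@carrierGroup == "case") caseIdx else ctrlIdx,
                      usedCarriers)
      if (spec@nCarriers > length(pool))
        stop("configuration error: more carriers requested than group members")
      carrierOf[[k]] <- sort(sample(pool, spec@nCarriers))
      usedCarriers <- c(usedCarriers, carrierOf[[k]])
    }

    rel <- injectRelatedness(G, freqB, config@nDuplicatePairs,
                             config@nParentOffspringPairs,
                             eligible = setdiff(seq_len(n), usedCarriers))
    G <- rel$genotypes
    relatedRole <- rep("none", n)
    if (nrow(rel$pairs)) {
      relatedRole[rel$pairs$member1] <- paste0(rel$pairs$type, "-1")
      relatedRole[rel$pairs$member2] <- paste0(rel$pairs$type, "-2")
    }

    ## allele copies: start diploid, then adjust carrier probes
    copiesB <- G
    copiesA <- 2L - G
    truthIntervals <- GRanges()
    carrierCopies <- list()
    for (k in seq_along(config@embeddedCnvs)) {
      spec <- config@embeddedCnvs[[k]]
      inCnv <- which(as.character(seqnames(manifest)) == spec@chromosome &
                     pos >= spec@start & pos <= spec@end)
      for (j in carrierOf[[k]]) {
        a <- copiesA[inCnv, j]; b <- copiesB[inCnv, j]
        cn <- spec@copyNumber
        if (cn == 3L) {
          extra <- rbinom(length(inCnv), 1L, freqB[inCnv])
          b <- b + extra; a <- a + (1L - extra)
        } else if (cn == 4L) {
          extra <- rbinom(length(inCnv), 2L, freqB[inCnv])
          b <- b + extra; a <- a + (2L - extra)
        } else if (cn == 1L) {
          dropB <- rbinom(length(inCnv), 1L, b / 2)
          b <- b - dropB; a <- a - (1L - dropB)
        } else if (cn == 0L) {
          a <- rep(0L, length(inCnv)); b <- rep(0L, length(inCnv))
        }
        copiesA[inCnv, j] <- a; copiesB[inCnv, j] <- b
        gr <- GRanges(spec@chromosome, IRanges(spec@start, spec@end),
                      sample = ids[j], copyNumber = cn)
        truthIntervals <- c(truthIntervals, gr)
        carrierCopies[[length(carrierCopies) + 1L]] <-
          data.frame(sample = ids[j], probe = mcols(manifest)$Name[inCnv],
                     copiesA = a, copiesB = b, copyNumber = cn)
      }
    }

    ## polar targets
    total <- copiesA + copiesB
    f <- ifelse(total > 0L, copiesB / pmax(total, 1L), 0.5)
    theta0 <- .thetaFromFraction(f, config@clusterThetaCenters)
    rm(f, copiesA, copiesB)
    Rdip <- 2 * log10(config@intensityScale)
    Rt <- (Rdip * (total + 0.1) / 2.1)^config@saturationGamma
    rm(total)

    ## per-sample GC wave on the log10 total-intensity scale
    gcc <- mcols(manifest)$GC - mean(mcols(manifest)$GC)
    waveCoef <- rnorm(n, 0, config@waveAmplitudeSd)
    Rt <- Rt + outer(gcc, waveCoef)

    ## split R across channels at the target theta, then add correlated
    ## lognormal channel noise
    t0 <- tanpi(pmin(pmax(theta0, 0), 0.999999) / 2)
    rm(theta0)
    x0 <- Rt / (1 + t0)
    y0 <- Rt - x0
    rm(t0, Rt)
    sdl <- config@noiseSdLog; rho <- config@channelCorr
    if (sdl > 0) {
      z0 <- matrix(rnorm(m * n), m, n)
      x0 <- x0 + sdl * sqrt(rho) * z0 + sdl * sqrt(1 - rho) *
        matrix(rnorm(m * n), m, n)
      y0 <- y0 + sdl * sqrt(rho) * z0 + sdl * sqrt(1 - rho) *
        matrix(rnorm(m * n), m, n)
      rm(z0)
    }
    x0 <- pmax(x0, 0)  # raw intensities floored at 1
    y0 <- pmax(y0, 0)
    X <- 10^x0; Y <- 10^y0
    thetaObs <- (2 / pi) * atan2(y0, x0)
    Robs <- x0 + y0
    rm(x0, y0)
    gcv <- gc(verbose = FALSE)

    ## generator-side genotype labels: posterior under three equal-weight
    ## Gaussians at the configured centers (the stand-in for an external
    ## caller); NC when the winning posterior drops below 0.9
    cal <- .labelGenotypes(thetaObs, config@clusterThetaCenters,
                           config@callConfSd)

    dimn <- list(mcols(manifest)$Name, ids)
    dimnames(X) <- dimnames(Y) <- dimnames(thetaObs) <- dimnames(Robs) <-
      dimnames(cal$genotype) <- dimnames(cal$conf) <- dimn

    truth <- list(intervals = truthIntervals, genotypes = G,
                  carrierCopies = if (length(carrierCopies))
                    do.call(rbind, carrierCopies) else NULL,
                  pairs = rel$pairs, waveCoef = waveCoef, config = config)
    SnpSignalSet(manifest,
                 assays = list(X = X, Y = Y, theta = thetaObs, R = Robs,
                               genotype = cal$genotype, genoConf = cal$conf),
                 colData = DataFrame(label = label, subpop = subpop,
                                     waveCoef = waveCoef,
                                     relatedRole = relatedRole,
                                     row.names = ids),
                 metadata = list(truth = truth))
  })
}

## Equal-weight three-Gaussian posterior caller on theta (memory-lean:
## works on squared distances, two running passes instead of stacked
## posterior matrices).
.labelGenotypes <- function(theta, centers, sdTheta) {
  d1 <- (theta - centers[1])^2
  d2 <- (theta - centers[2])^2
  d3 <- (theta - centers[3])^2
  dmin <- pmin(d1, d2, d3)
  geno <- (d2 <= d1 & d2 <= d3) * 1L
  geno[d3 < d1 & d3 < d2] <- 2L
  ## winning posterior = 1 / sum_k exp(-(dk - dmin)/(2 sd^2))
  s2 <- 2 * sdTheta^2
  tot <- exp(-(d1 - dmin) / s2) + exp(-(d2 - dmin) / s2) +
    exp(-(d3 - dmin) / s2)
  rm(d1, d2, d3, dmin)
  conf <- 1 - 1 / tot
  geno[conf > 0.1] <- NA
  storage.mode(geno) <- "integer"
  list(genotype = geno, conf = conf)
}

#' Simulate LRR/BAF tracks directly from a CnvHmm model
#'
#' Samples per-probe hidden state paths from the model's distance-dependent
#' Markov chain and emits LRR and BAF from the state emission densities —
#' used for training-recovery checks against a known generating model.
#'
#' @param model a [CnvHmm].
#' @param manifest a [SnpManifest] supplying probe positions.
#' @param pfb per-probe population B-allele frequency.
#' @param nSamples number of samples.
#' @param seed integer seed.
#' @param initState initial-state probabilities (defaults to near-diploid).
#' @return `list(lrr =, baf =, states =)` with probes-x-samples matrices.
#' @export
simulateFromModel <- function(model, manifest, pfb, nSamples, seed = 1L,
                              initState = NULL) {
  stopifnot(is(model, "CnvHmm"))
  m <- length(manifest)
  pos <- start(manifest)
  pi0 <- initState %||% c(1e-4, 1e-3, 0.9949, 1e-3, 2e-3, 1e-4)
  pi0 <- pi0 / sum(pi0)
  withSeed(seed, {
    lrr <- matrix(NA_real_, m, nSamples)
    baf <- matrix(NA_real_, m, nSamples)
    st <- matrix(NA_integer_, m, nSamples)
    trans <- lapply(diff(pos), transitionMatrix, model = model)
    for (j in seq_len(nSamples)) {
      s <- integer(m)
      s[1] <- sample.int(6L, 1L, prob = pi0)
      for (t in 2:m) s[t] <- sample.int(6L, 1L, prob = trans[[t - 1L]][s[t - 1L], ])
      st[, j] <- s
      lrr[, j] <- rnorm(m, model@lrrMean[s], model@lrrSd[s])
      baf[, j] <- .sampleBafBands(s, pfb, model@bafSd)
    }
    list(lrr = lrr, baf = baf, states = st)
  })
}

.sampleBafBands <- function(states, pfb, bafSd) {
  m <- length(states)
  out <- numeric(m)
  for (t in seq_len(m)) {
    bw <- .bafBands(states[t], pfb[t])
    band <- sample(bw$bands, 1L, prob = bw$weights)
    out[t] <- if (states[t] == 1L) runif(1) else
      min(1, max(0, rnorm(1, band, bafSd)))
  }
  out
}
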