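test_that("emission log-densities rank states by their band structure", {
  model <- cnvHmmDefaults()
  ## a clean heterozygote favours the diploid state over CN1 (no 0.5 band)
  e <- emissionLogProb(model, 0, 0.5, 0.5)
  expect_gt(e[1, "CN2"], e[1, "CN1"])
  ## AAB band with elevated LRR favours CN3
  e2 <- emissionLogProb(model, 0.4, 1/3, 0.5)
  expect_gt(e2[1, "CN3"], e2[1, "CN2"])
  ## het-free probes at diploid intensity favour CN2-LOH pointwise
  for (b in c(0, 1)) {
    e3 <- emissionLogProb(model, 0, b, 0.5)
    expect_gt(e3[1, "CN2-LOH"], e3[1, "CN2"])
  }
  ## masked BAF drops its term: emission equals the LRR-only density
  e4 <- emissionLogProb(model, 0.2, NA, 0.5)
  eps <- model@outlierFrac
  expect_equal(unname(e4[1, ]),
               log((1 - eps) * dnorm(0.2, model@lrrMean, model@lrrSd) +
                   eps * 0.1),
               tolerance = 1e-12)
})

test_that("distance-dependent transitions are stochastic and monotone", {
  model <- cnvHmmDefaults()
  for (d in c(1, 500, 1e4, 1e6)) {
    tm <- transitionMatrix(d, model)
    expect_equal(unname(rowSums(tm)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(tm >= 0))
  }
  ## large-distance limit recovers the base matrix
  expect_equal(unname(transitionMatrix(1e9, model)),
               unname(model@transBase), tolerance = 1e-9)
  ## self-transition maximal at clamped d = 0, non-increasing in d
  stay <- vapply(c(1, 10, 100, 1e3, 1e4, 1e5, 1e6), function(d)
    transitionMatrix(d, model)["CN3", "CN3"], numeric(1))
  expect_true(all(diff(stay) <= 1e-15))
})

test_that("Viterbi equals exhaustive enumeration on short chromosomes", {
  model <- cnvHmmDefaults()
  set.seed(42)
  logpi <- log(cnvarray:::.hmmInit())
  for (rep in 1:12) {
    T <- sample(4:7, 1)
    pos <- sort(sample.int(5e5, T))
    lrr <- rnorm(T, sample(c(0, 0.4, -0.66), T, replace = TRUE), 0.3)
    baf <- runif(T)
    pfb <- runif(T, 0.2, 0.8)
    logem <- emissionLogProb(model, lrr, baf, pfb)
    tc <- cnvarray:::.transCube(pos, model)
    vp <- cnvarray:::.viterbi_cpp(logem, tc$cube, logpi)
    expect_equal(unname(vp), unname(enumerateBestPath(logem, pos, model)))
  }
})

test_that("clean diploid samples yield no calls; spikes are absorbed", {
  cfg <- simulationConfig(seed = 2L, nCases = 10L, nControls = 10L,
                          nProbes = 300L, noiseSdLog = 0,
                          waveAmplitudeSd = 0)
  man <- simulateManifest(cfg)
  coh <- simulateCohort(cfg, man)
  cl <- buildClusters(coh)
  coh <- deriveSignal(coh, cl)
  pfb <- computePFB(assay(coh, "baf"), usable = cl@usable)
  calls <- callCnvs(coh, pfb)
  expect_length(calls, 0L)

  ## single-probe LRR spike at -3 between diploid probes at 1 kb spacing
  model <- cnvHmmDefaults()
  T <- 41L
  pos <- seq(1e5, by = 1000L, length.out = T)
  lrr <- rep(0, T); lrr[21L] <- -3
  baf <- rep(c(0, 0.5, 1), length.out = T)
  man1 <- SnpManifest(sprintf("s%02d", 1:T), "chr1", pos, rep(0.4, T))
  calls1 <- callCnvs(list(lrr = matrix(lrr, dimnames = list(NULL, "x")),
                          baf = matrix(baf, dimnames = list(NULL, "x")),
                          manifest = man1),
                     pfb = rep(0.5, T), model = model)
  expect_length(calls1, 0L)
})

test_that("an embedded duplication is recovered with accurate breakpoints", {
  fx <- smallFixture()
  truth <- metadata(fx$cohort)$truth
  carriers <- unique(mcols(truth$intervals)$sample)
  calls <- callCnvs(fx$cohort, fx$pfb, samples = carriers)
  expect_length(calls, 5L)
  expect_true(all(mcols(calls)$state == "CN3"))
  expect_true(all(mcols(calls)$conf > 0))
  ## boundaries within +/- 2 probes of the first/last carrier probe
  pos <- start(fx$manifest)
  inIdx <- which(pos >= 1200001 & pos <= 1846850)
  for (k in seq_along(calls)) {
    i1 <- match(start(calls)[k], pos); i2 <- match(end(calls)[k], pos)
    expect_lte(abs(i1 - min(inIdx)), 2L)
    expect_lte(abs(i2 - max(inIdx)), 2L)
  }
  ## calls never overlap within a sample
  for (s in carriers) {
    cs <- calls[mcols(calls)$sample == s]
    expect_true(isDisjoint(cs))
  }
})

test_that("calls are invariant to prepending/appending diploid stretches", {
  model <- cnvHmmDefaults()
  set.seed(77)
  Tseg <- 60L
  core <- list(
    lrr = c(rnorm(50, 0, 0.15), rnorm(Tseg, 0.4, 0.15), rnorm(50, 0, 0.15)),
    baf = c(ifelse(runif(50) < 0.5, sample(c(0, 1), 50, TRUE), 0.5),
            sample(c(0, 1/3, 2/3, 1), Tseg, TRUE),
            ifelse(runif(50) < 0.5, sample(c(0, 1), 50, TRUE), 0.5)))
  pad <- function(n) list(lrr = rnorm(n, 0, 0.15),
                          baf = sample(c(0, 0.5, 1), n, TRUE,
                                       prob = c(0.25, 0.5, 0.25)))
  decode <- function(lrr, baf, offset) {
    T <- length(lrr)
    pos <- seq(1e5 + offset * 1500L, by = 1500L, length.out = T)
    man <- SnpManifest(sprintf("p%04d", seq_len(T) + offset), "chr1", pos,
                       rep(0.4, T))
    ## positions are already aligned across paddings via the offset
    callCnvs(list(lrr = matrix(lrr, dimnames = list(NULL, "x")),
                  baf = matrix(baf, dimnames = list(NULL, "x")),
                  manifest = man), rep(0.5, T), model)
  }
  base <- decode(c(pad(0)$lrr, core$lrr), c(pad(0)$baf, core$baf), 0L)
  p1 <- pad(40L); p2 <- pad(40L)
  padded <- decode(c(p1$lrr, core$lrr, p2$lrr),
                   c(p1$baf, core$baf, p2$baf), -40L)
  expect_equal(length(base), 1L)
  expect_equal(length(padded), 1L)
  expect_equal(start(base), start(padded))
  expect_equal(end(base), end(padded))
})

test_that("training recovers the generating LRR mean and keeps EM monotone", {
  cfg <- simulationConfig(seed = 3L, nProbes = 500L)
  man <- simulateManifest(cfg)
  pfb <- mcols(man)$FreqB
  truthModel <- cnvHmmDefaults()
  sim <- simulateFromModel(truthModel, man, pfb, nSamples = 95L, seed = 5L)
  start <- cnvHmm(lrrMean = c(-3.5, -0.66, 0, 0, 0.30, 0.55),
                  lrrSd = c(1.3, 0.3, 0.2, 0.2, 0.25, 0.3))
  tr <- trainHmm(list(lrr = sim$lrr, baf = sim$baf, manifest = man), pfb,
                 model = start, seed = 9L)
  expect_equal(tr@lrrMean[5], truthModel@lrrMean[5], tolerance = 0.05)
  for (lls in attr(tr, "loglik"))
    expect_true(all(diff(lls) > -(1e-3 * abs(lls[-length(lls)]) + 1)))
  expect_error(trainHmm(list(lrr = sim$lrr[, 1:10], baf = sim$baf[, 1:10],
                             manifest = man), pfb), "at least 30")
})

test_that("training on diploid-only data shrinks CNV transition mass", {
  cfg <- simulationConfig(seed = 6L, nCases = 20L, nControls = 20L,
                          nProbes = 400L)
  man <- simulateManifest(cfg)
  coh <- simulateCohort(cfg, man)
  cl <- buildClusters(coh)
  coh <- deriveSignal(coh, cl)
  pfb <- computePFB(assay(coh, "baf"), usable = cl@usable)
  m0 <- cnvHmmDefaults()
  tr <- trainHmm(coh, pfb, model = m0, nBatches = 1L, maxIter = 4L,
                 seed = 2L)
  cnvMass <- function(m) sum(m@transBase[3, c(1, 2, 5, 6)])
  expect_lt(cnvMass(tr), cnvMass(m0))
})

test_that("model round-trips through the text serialization", {
  m <- cnvHmm(lrrMean = c(-3.2, -0.6, 0, 0, 0.38, 0.7),
              lrrSd = c(1.2, 0.25, 0.18, 0.18, 0.2, 0.22), bafSd = 0.05)
  f <- tempfile(fileext = ".hmm")
  writeHmmModel(m, f)
  m2 <- readHmmModel(f)
  expect_equal(m@lrrMean, m2@lrrMean)
  expect_equal(m@transBase, m2@transBase, tolerance = 1e-12)
  expect_equal(m@bafSd, m2@bafSd)
})
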