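test_that("the polar transform matches its closed form", {
  expect_equal(toPolar(1000, 1000), list(theta = 0.5, R = 6))
  expect_equal(toPolar(1000, 1), list(theta = 0, R = 3))
  p <- toPolar(10, 1000)
  expect_equal(p$theta, (2 / pi) * atan2(3, 1), tolerance = 1e-12)
  expect_equal(p$R, 4)
  ## sub-1 intensities are floored (both channels at the floor collapse
  ## to the atan2(0, 0) = 0 convention), non-finite inputs masked not fatal
  expect_equal(toPolar(0.5, 0.5), list(theta = 0, R = 0))
  m <- toPolar(c(100, NA, Inf), c(100, 50, 10))
  expect_true(all(is.na(m$theta[2:3])) && all(is.na(m$R[2:3])))
})

test_that("cluster building recovers true centers and imputes sanely", {
  set.seed(4)
  n <- 500L
  centers <- c(0.1, 0.5, 0.9)
  g <- rbind(rbinom(n, 2L, 0.45), rbinom(n, 2L, 0.5))
  theta <- matrix(centers[g + 1L] + rnorm(2L * n, 0, 0.02), 2L, n)
  R <- matrix(3.5 + rnorm(2L * n, 0, 0.05), 2L, n)
  cl <- buildClusters(list(theta = theta, R = R, genotype = g,
                           genoConf = matrix(0, 2L, n)))
  expect_true(all(cl@usable))
  expect_equal(unname(cl@theta[1, ]), centers, tolerance = 0.01)
  expect_equal(unname(cl@theta[2, ]), centers, tolerance = 0.01)

  ## SNP with no AB calls: theta_AB imputed at the homozygote midpoint
  g2 <- matrix(ifelse(g[1, ] == 1L, 0L, g[1, ]), 1L)
  cl2 <- buildClusters(list(theta = theta[1, , drop = FALSE],
                            R = R[1, , drop = FALSE], genotype = g2,
                            genoConf = matrix(0, 1L, n)))
  expect_true(cl2@usable[1])
  expect_true(cl2@imputed[1, "AB"])
  expect_equal(cl2@theta[1, "AB"],
               (cl2@theta[1, "AA"] + cl2@theta[1, "BB"]) / 2)
  expect_equal(cl2@R[1, "AB"], max(cl2@R[1, c("AA", "BB")]))

  ## monomorphic SNP is unusable; all-NC SNP is unusable without error
  g3 <- matrix(0L, 1L, n)
  cl3 <- buildClusters(list(theta = theta[1, , drop = FALSE],
                            R = R[1, , drop = FALSE], genotype = g3,
                            genoConf = matrix(0, 1L, n)))
  expect_false(cl3@usable[1])
  g4 <- matrix(NA_integer_, 1L, n)
  cl4 <- buildClusters(list(theta = theta[1, , drop = FALSE],
                            R = R[1, , drop = FALSE], genotype = g4,
                            genoConf = matrix(0, 1L, n)))
  expect_false(cl4@usable[1])
  expect_error(buildClusters(list(theta = theta[, 0, drop = FALSE],
                                  R = R[, 0, drop = FALSE],
                                  genotype = g[, 0, drop = FALSE],
                                  genoConf = matrix(0, 2L, 0))),
               "no samples")
})

test_that("BAF interpolation hits its anchors and is monotone in theta", {
  cl <- new("GenotypeClusters", snp = "s1",
            theta = matrix(c(0.1, 0.5, 0.9), 1L), R = matrix(3.5, 1L, 3L),
            counts = matrix(5L, 1L, 3L), usable = TRUE,
            imputed = matrix(FALSE, 1L, 3L))
  expect_equal(deriveBAF(matrix(0.1, 1L), cl)[1], 0)
  expect_equal(deriveBAF(matrix(0.5, 1L), cl)[1], 0.5)
  expect_equal(deriveBAF(matrix(0.9, 1L), cl)[1], 1)
  expect_equal(deriveBAF(matrix(0.7, 1L), cl)[1], 0.75)   # midway AB-BB
  expect_equal(deriveBAF(matrix(0.05, 1L), cl)[1], 0)     # clamped below AA
  grid <- matrix(seq(0, 1, length.out = 101), 1L)
  vals <- vapply(grid[1, ], function(t) deriveBAF(matrix(t, 1L), cl)[1],
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("LRR is the log2 ratio against the interpolated cluster R", {
  cl <- new("GenotypeClusters", snp = "s1",
            theta = matrix(c(0.1, 0.5, 0.9), 1L),
            R = matrix(c(3.0, 3.6, 3.2), 1L),
            counts = matrix(5L, 1L, 3L), usable = TRUE,
            imputed = matrix(FALSE, 1L, 3L))
  expect_equal(deriveLRR(matrix(0.5, 1L), matrix(3.6, 1L), cl)[1], 0)
  expect_equal(deriveLRR(matrix(0.5, 1L), matrix(7.2, 1L), cl)[1], 1)
  ## interpolated expectation midway between AA and AB anchors
  expect_equal(deriveLRR(matrix(0.3, 1L), matrix(3.3, 1L), cl)[1],
               log2(3.3 / 3.3))
  ## beyond the BB center the expectation clamps at R_BB
  expect_equal(deriveLRR(matrix(0.95, 1L), matrix(3.2, 1L), cl)[1], 0)
  ## unusable cluster masks
  cl@usable <- FALSE
  expect_true(is.na(deriveLRR(matrix(0.5, 1L), matrix(3.6, 1L), cl)[1]))
})

test_that("round-trip: noiseless diploid signals give exact BAF and zero LRR", {
  cfg <- simulationConfig(seed = 8L, nCases = 30L, nControls = 30L,
                          nProbes = 60L, noiseSdLog = 0, waveAmplitudeSd = 0)
  man <- simulateManifest(cfg)
  coh <- simulateCohort(cfg, man)
  cl <- buildClusters(coh)
  coh <- deriveSignal(coh, cl)
  G <- metadata(coh)$truth$genotypes
  baf <- assay(coh, "baf"); lrr <- assay(coh, "lrr")
  u <- cl@usable
  expect_equal(unname(baf[u, ]), matrix(c(0, 0.5, 1)[G[u, ] + 1L],
                                        sum(u), ncol(coh)),
               tolerance = 1e-9)
  expect_equal(max(abs(lrr[u, ]), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("quantile Log2Ratio removes global shifts and flags real gains", {
  set.seed(10)
  tot <- matrix(runif(300, 500, 3000), 100L, 3L)
  same <- log2RatioQuantile(cbind(tot[, 1], tot[, 1], tot[, 1]))
  expect_equal(max(abs(same)), 0, tolerance = 1e-12)
  ## doubling one sample everywhere is removed by quantile normalization
  doubled <- cbind(tot[, 1:2], tot[, 3])
  doubled[, 3] <- doubled[, 3] * 2
  l2r <- log2RatioQuantile(doubled)
  expect_lt(max(abs(colMeans(l2r))), 0.05)
  ## a single elevated probe stands out positively only in that sample;
  ## elsewhere the signal is (rank-boundary effects aside) flat
  tot2 <- matrix(rep(tot[, 1], 3L), ncol = 3L)
  tot2[7L, 3L] <- tot2[7L, 3L] * 4
  l2r2 <- log2RatioQuantile(tot2)
  expect_gt(l2r2[7L, 3L], 0.5)
  expect_equal(unname(l2r2[7L, 1:2]), c(0, 0), tolerance = 1e-8)
  expect_equal(median(abs(l2r2[-7L, ])), 0, tolerance = 1e-8)
  expect_lt(mean(abs(l2r2[-7L, ]) > 0.1), 0.02)
  expect_error(log2RatioQuantile(tot[, 1, drop = FALSE]), "2 samples")
})

test_that("PFB is the clipped mean BAF", {
  baf <- rbind(rep(1, 10), rep(0, 10), rep(0.5, 10))
  pfb <- computePFB(baf)
  expect_equal(unname(pfb), c(0.99, 0.01, 0.5))
  ## HWE at freq 0.5: PFB ~ 0.5 within 3 SE across samples
  fx <- smallFixture()
  fq <- mcols(fx$manifest)$FreqB
  mid <- which(abs(fq - 0.5) < 0.02 & fx$clusters@usable)
  expect_gt(length(mid), 5L)
  se <- sqrt(0.5 * 0.5 / (2 * ncol(fx$cohort)))
  devs <- abs(fx$pfb[mid] - fq[mid])
  expect_true(mean(devs < 3 * (se + 0.01)) > 0.9)
})

test_that("the fallback genotype caller matches generator truth", {
  cfg <- simulationConfig(seed = 21L, nCases = 100L, nControls = 100L,
                          nProbes = 120L, noiseSdLog = 0.03,
                          channelCorr = 0)
  man <- simulateManifest(cfg)
  coh <- simulateCohort(cfg, man)
  cg <- callGenotypes(assay(coh, "theta"))
  expect_true(all(cg$converged))
  truthG <- metadata(coh)$truth$genotypes
  ok <- !is.na(cg$genotype)
  expect_gt(mean(cg$genotype[ok] == truthG[ok]), 0.99)
  expect_error(callGenotypes(assay(coh, "theta")[, 1:5]), ">= 10 samples")
})

test_that("a sample midway between two equal components is a no-call", {
  set.seed(2)
  th <- matrix(c(rnorm(200, 0.15, 0.03), rnorm(200, 0.5, 0.03),
                 rnorm(200, 0.85, 0.03), 0.325), 1L)
  cg <- callGenotypes(th)
  expect_true(is.na(cg$genotype[1, 601L]))
  expect_gte(cg$conf[1, 601L], 0.4)
})

test_that("the default fixture keeps >= 95% of SNPs usable", {
  fx <- smallFixture()
  expect_gte(usableFraction(fx$clusters), 0.95)
})
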