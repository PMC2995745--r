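## Shared fixtures, built in code.  Sizes are kept small: the study-scale
## reconstruction lives in the acceptance tests only.

## small cohort with the canonical duplication, cached per test run
smallFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(
        seed = 7L, nCases = 150L, nControls = 250L, nProbes = 800L,
        chromLength = 3e6,
        embeddedCnvs = list(cnvSpec(start = 1200001, end = 1846850,
                                    copyNumber = 3L, carrierGroup = "case",
                                    nCarriers = 5L)))
      man <- simulateManifest(cfg)
      coh <- simulateCohort(cfg, man)
      cl <- buildClusters(coh)
      coh <- deriveSignal(coh, cl)
      pfb <- computePFB(assay(coh, "baf"), usable = cl@usable)
      cache <<- list(config = cfg, manifest = man, cohort = coh,
                     clusters = cl, pfb = pfb)
    }
    cache
  }
})

## vectorized brute-force scorer over all 6^T state sequences
enumerateBestPath <- function(logem, pos, model) {
  T <- nrow(logem)
  tc <- cnvarray:::.transCube(pos, model)
  logpi <- log(cnvarray:::.hmmInit())
  grid <- as.matrix(expand.grid(rep(list(1:6), T)))
  sc <- logpi[grid[, 1]] + logem[cbind(1L, grid[, 1])]
  for (t in 2:T) {
    sc <- sc + tc$cube[cbind(grid[, t - 1L], grid[, t], t - 1L)] +
      logem[cbind(t, grid[, t])]
  }
  grid[which.max(sc), ]
}

## UCSC-style cytoband fixture for a 3 Mb synthetic chromosome
cytobandFixture <- function(path) {
  writeLines(c("chr5\t0\t200000\tp15.3\tgneg",
               "chr5\t200000\t1400000\tp15.2\tgpos50",
               "chr5\t1400000\t1500000\tp11\tacen",
               "chr5\t1500000\t1600000\tq11\tacen",
               "chr5\t1600000\t2800000\tq12\tgneg",
               "chr5\t2800000\t3000000\tq13\tgneg"), path)
  path
}
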