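mkCall <- function(chrom, start, end, sample, cn = 3L, numsnp = 20L) {
  GRanges(chrom, IRanges(start, end), sample = sample,
          state = names(which(cnvarray:::HMM_COPYNUMBER == cn))[1],
          cn = as.integer(cn), numsnp = as.integer(numsnp),
          startSnp = "a", endSnp = "b", conf = 10)
}

test_that("size filter is inclusive at both thresholds", {
  calls <- new("CnvCalls", c(
    mkCall("chr5", 1e5, 3e5, "s1", numsnp = 9L),          # fails SNP floor
    mkCall("chr5", 1e5, 199998L, "s2", numsnp = 10L),     # 99,999 bp < 100 kb
    mkCall("chr5", 1e5, 199999L, "s3", numsnp = 10L),     # exactly 100 kb
    mkCall("chr5", 168423758L, 169070607L, "s4", numsnp = 198L)))
  kept <- sizeFilter(calls)
  expect_setequal(mcols(kept)$sample, c("s3", "s4"))
  expect_equal(width(kept[mcols(kept)$sample == "s4"]), 646850L)
})

test_that("carrier tabulation counts each sample once per SNP", {
  man <- SnpManifest(c("r1", "r2", "r3"), "chr5",
                     c(100L, 500L, 900L), rep(0.4, 3L))
  labels <- setNames(c("case", "case", "control"), c("s1", "s2", "c1"))
  calls <- new("CnvCalls", c(
    mkCall("chr5", 50L, 600L, "s1"),
    mkCall("chr5", 80L, 550L, "s1"),       # overlapping call, same sample
    mkCall("chr5", 400L, 950L, "s2"),
    mkCall("chr5", 850L, 950L, "c1", cn = 1L)))
  cm <- carrierMatrix(calls, man, labels)
  expect_equal(unname(cm@counts[, "case", "dup"]), c(1L, 2L, 1L))
  expect_equal(unname(cm@counts[, "control", "dup"]), c(0L, 0L, 0L))
  expect_equal(unname(cm@counts[, "control", "del"]), c(0L, 0L, 1L))
  expect_equal(sort(unname(unlist(cm@carriers$dup$case[[2]]))),
               c("s1", "s2"))
  expect_error(carrierMatrix(calls, man, labels[1:2]), "unlabeled")
})

test_that("the one-sided Fisher tail matches enumeration and phyper", {
  ## full-table agreement at n <= 50, 1e-12 relative tolerance
  set.seed(1)
  for (rep in 1:200) {
    nCase <- sample(1:25, 1); nCtrl <- sample(1:25, 1)
    a <- sample(0:nCase, 1); b <- sample(0:nCtrl, 1)
    p <- fisherCarrier(a, nCase, b, nCtrl)
    k <- a + b
    enum <- if (k == 0) 1 else sum(vapply(a:min(k, nCase), function(j)
      choose(nCase, j) * choose(nCtrl, k - j), numeric(1))) /
      choose(nCase + nCtrl, k)
    expect_equal(p, min(1, enum), tolerance = 1e-12)
    expect_equal(p, stats::phyper(a - 1, nCase, nCtrl, k,
                                  lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_equal(fisherCarrier(0, 10, 0, 10), 1)
  expect_equal(fisherCarrier(0, 10, 5, 10), 1)
  ## study-scale worked example: 5/1693 cases vs 0/4506 controls
  expect_equal(fisherCarrier(5, 1693, 0, 4506),
               prod((1693 - 0:4) / (6199 - 0:4)), tolerance = 1e-12)
})

test_that("CNVR formation merges by window and finds the local minimum", {
  m <- 5L
  man <- SnpManifest(sprintf("r%d", 1:m), "chr5",
                     c(1e5, 2e5, 1.1e6, 2.4e6, 2.5e6), rep(0.4, m))
  mkCm <- function(aCnt) {
    counts <- array(0L, c(m, 2, 2),
                    dimnames = list(NULL, c("case", "control"),
                                    c("dup", "del")))
    counts[, 1, 1] <- aCnt
    carriers <- list(dup = list(
      case = as(lapply(aCnt, function(k) sprintf("case%02d", seq_len(k))),
                "CharacterList"),
      control = as(rep(list(character()), m), "CharacterList")),
      del = list(case = as(rep(list(character()), m), "CharacterList"),
                 control = as(rep(list(character()), m), "CharacterList")))
    new("CarrierMatrix", manifest = man, counts = counts,
        carriers = carriers, nCase = 100L, nCtrl = 200L)
  }
  ## significant SNPs at 1e5, 2e5 (0.1 Mb apart) and 1.1e6 (0.9 Mb from
  ## the last) merge into one region; 2.4e6 is 1.3 Mb away: a new region
  cm <- mkCm(c(4L, 6L, 4L, 4L, 0L))
  regs <- formCnvrs(cm, alpha = 0.05, exclusiveOnly = FALSE)
  expect_length(regs, 2L)
  expect_equal(start(regs), c(1e5, 2.4e6))
  expect_equal(end(regs), c(1.1e6, 2.4e6))
  ## peak at the smallest p = largest count
  expect_equal(mcols(regs)$peakSnp[1], "r2")
  expect_equal(mcols(regs)$caseCarriers[1], 6L)
  expect_true(all(mcols(regs)$exclusive))
  ## two significant SNPs 1.1 Mb apart split
  man2 <- SnpManifest(c("a", "b"), "chr5", c(1e5, 1.2e6), rep(0.4, 2))
  cm2 <- mkCm(c(4L, 4L, 0L, 0L, 0L))
  cm2@manifest <- man2
  cm2@counts <- cm2@counts[1:2, , , drop = FALSE]
  cm2@carriers$dup$case <- cm2@carriers$dup$case[1:2]
  cm2@carriers$dup$control <- cm2@carriers$dup$control[1:2]
  cm2@carriers$del$case <- cm2@carriers$del$case[1:2]
  cm2@carriers$del$control <- cm2@carriers$del$control[1:2]
  expect_length(formCnvrs(cm2, exclusiveOnly = FALSE), 2L)
})

test_that("CNVR formation is invariant to SNP input order and disjoint", {
  fx <- smallFixture()
  truth <- metadata(fx$cohort)$truth
  labels <- sampleLabels(fx$cohort)
  calls <- sizeFilter(callCnvs(fx$cohort, fx$pfb))
  cm <- carrierMatrix(calls, fx$manifest, labels)
  regs <- formCnvrs(cm)
  expect_length(regs, 1L)
  expect_true(mcols(regs)$exclusive[1])
  expect_equal(mcols(regs)$caseCarriers[1], 5L)
  expect_setequal(unlist(mcols(regs)$caseIds),
                  unique(mcols(truth$intervals)$sample))
  ## seeded interval covered by the region
  expect_lte(start(regs), 1200001 + 20000)
  expect_gte(end(regs), 1846850 - 20000)
  ## shuffled manifest order gives the identical region set
  set.seed(2)
  ord <- sample(length(fx$manifest))
  manS <- fx$manifest[ord]
  manS <- new("SnpManifest", sort(manS))
  cmS <- carrierMatrix(calls, manS, labels)
  regsS <- formCnvrs(cmS)
  expect_equal(start(regs), start(regsS))
  expect_equal(end(regs), end(regsS))
  expect_true(isDisjoint(regs))
})

test_that("exclusion rules flag cytoband, peninsula, GC and shared samples", {
  f <- tempfile()
  cyto <- readCytoband(cytobandFixture(f))
  man <- SnpManifest(sprintf("r%d", 1:6), "chr5",
                     c(1.45e6, 1.46e6, 2.0e6, 2.05e6, 2.6e6, 2.65e6),
                     c(0.7, 0.7, 0.45, 0.45, 0.45, 0.45))
  mkRegion <- function(s, e, ids, peak) {
    gr <- GRanges("chr5", IRanges(s, e), peakSnp = "x", peakPos = peak,
                  nSnps = 2L, caseCarriers = length(ids),
                  ctrlCarriers = 0L, caseIds = CharacterList(list(ids)),
                  pFisher = 0.01, pPerm = NA_real_, exclusive = TRUE)
    new("CnvRegions", gr)
  }
  ## inside an acen band + high GC
  rAcen <- mkRegion(1.45e6, 1.46e6, "s1", 1.45e6)
  ## clean region
  rOk <- mkRegion(2.0e6, 2.05e6, "s2", 2.0e6)
  ## shares boundary with a common CNV; shares a sample with rAcen
  rPen <- mkRegion(2.6e6, 2.65e6, c("s1", "s3"), 2.6e6)
  regs <- suppressWarnings(c(rAcen, rOk, rPen))
  common <- GRanges("chr5", IRanges(2.59e6, 2.8e6), freq = 0.05)
  out <- applyExclusionRules(new("CnvRegions", regs), cytobands = cyto,
                             manifest = man, commonCnv = common)
  mc <- mcols(out)
  expect_equal(mc$flagTelomereCentromere, c(TRUE, FALSE, FALSE))
  expect_equal(mc$flagGcExtreme, c(TRUE, FALSE, FALSE))
  expect_equal(mc$flagPeninsula, c(FALSE, FALSE, TRUE))
  expect_equal(mc$flagMultiCnvr, c(TRUE, FALSE, TRUE))
  expect_equal(mc$anyFlag, c(TRUE, FALSE, TRUE))
  ## without a cytoband table rule i is unknown, others still evaluated
  out2 <- applyExclusionRules(new("CnvRegions", regs), cytobands = NULL,
                              manifest = man, commonCnv = common)
  expect_true(all(is.na(mcols(out2)$flagTelomereCentromere)))
  expect_equal(mcols(out2)$flagPeninsula, c(FALSE, FALSE, TRUE))
})

test_that("permutation p matches the hypergeometric closed form", {
  labels <- setNames(rep(c("case", "control"), c(150, 250)),
                     sprintf("s%03d", 1:400))
  carriers <- names(labels)[c(3, 10, 22, 40, 77)]   # five case carriers
  pt <- permutationTest(carriers, labels, nPerm = 4000L, seed = 4L)
  exact <- prod((150 - 0:4) / (400 - 0:4))
  mcse <- sqrt(exact * (1 - exact) / 4000)
  expect_equal(pt$observed, 5L)
  expect_lt(abs(pt$p - exact), 3 * mcse + 1 / 4000)
  ## determinism and degenerate cases
  expect_equal(pt$p, permutationTest(carriers, labels, 4000L, seed = 4L)$p)
  mixed <- names(labels)[c(3, 390)]                 # case + control carrier
  expect_equal(permutationTest(mixed, labels, 500L)$p, 1)
  expect_warning(permutationTest(carriers, labels, nPerm = 50L), "100")
})

test_that("the contamination estimate applies prevalence and rounds", {
  est <- contaminationEstimate(0.16, 1600 + 1209, nControlsTotal = 4506)
  expect_equal(est$expected, 449)
  expect_equal(est$fraction, 449 / 4506, tolerance = 1e-12)
  expect_equal(contaminationEstimate(0, 1000)$expected, 0)
  expect_equal(contaminationEstimate(0.5, 100)$expected, 50)
})
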