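test_that("constrained Ward reproduces the full Lance-Williams oracle", {
  withr::with_seed(17, {
    for (t in 1:100) {
      n <- sample(10:30, 1)
      z <- matrix(rnorm(n * 2), n, 2)
      ncl <- sample(2:max(2, n %/% 2), 1)
      fast <- segmentSizes(constrainedSegmentation(z, ncl))
      slow <- oracleConstrainedWard(z, ncl)
      expect_identical(as.integer(fast), as.integer(slow))
    }
  })
})

test_that("segmentation degenerate cases and contiguity hold", {
  z <- matrix(rnorm(40), 20, 2)
  s1 <- constrainedSegmentation(z, 1L)
  expect_equal(segmentSizes(s1), 20L)
  sN <- constrainedSegmentation(z, 20L)
  expect_equal(segmentSizes(sN), rep(1L, 20))
  expect_error(constrainedSegmentation(z, 21L), "nClusters")
  # contiguity: segment table covers [0, N) without gaps
  withr::with_seed(3, {
    for (i in 1:25) {
      n <- sample(15:60, 1)
      z <- matrix(rnorm(n * 3), n, 3)
      s <- constrainedSegmentation(z, sample(1:n, 1))
      tab <- segmentTable(s)
      expect_equal(tab$startBin[1], 0L)
      expect_equal(tab$endBin[nrow(tab)], n)
      if (nrow(tab) > 1)
        expect_equal(tab$startBin[-1], tab$endBin[-nrow(tab)])
    }
  })
})

test_that("cluster count comes from chromosome length / average size", {
  expect_equal(nClustersForChrom(10e6, 20L), 50L)   # 10 Mb / 200 kb
  expect_equal(nClustersForChrom(1.99e6, 20L), 9L)  # floor
  expect_equal(nClustersForChrom(5e4, 20L), 1L)     # never below 1
})

test_that("CTCF boundary filter keeps the high-count group", {
  seg <- SegmentationResult(boundaries = c(4L, 9L, 14L, 19L, 24L),
                            nBins = 30L)
  ctcf <- integer(30)
  ctcf[c(4, 9, 14, 19, 24) + 1L] <- c(0L, 0L, 0L, 5L, 6L)
  filt <- ctcfBoundaryFilter(seg, ctcf)
  expect_equal(boundaryBins(filt), c(19L, 24L))
  # dropped boundaries merge their flanking segments
  expect_equal(segmentSizes(filt), c(19L, 5L, 6L))
  # all-equal counts: no split possible
  ctcf[c(4, 9, 14, 19, 24) + 1L] <- 3L
  expect_warning(same <- ctcfBoundaryFilter(seg, ctcf), "equal CTCF")
  expect_equal(boundaryBins(same), boundaryBins(seg))
})

test_that("CTCF filtering enriches for true boundaries on synthetic data", {
  tr <- simulateTruth(300, nLoops = 10, seed = 41)
  gen <- simulateGenome(tr, seed = 42)
  ctcf <- motifCounts(NULL, "chrS", 300)  # start from zero, add planted
  ctcf[gen@ctcfPositions + 1L] <- 1L
  truthB <- truthBoundaries(tr)
  # candidates: true boundaries plus noise bins without motifs
  withr::with_seed(43, {
    noise <- sample(setdiff(1:299, c(gen@ctcfPositions, truthB)), 15)
  })
  cand <- sort(unique(c(truthB, noise)))
  seg <- SegmentationResult(boundaries = cand, nBins = 300L)
  filt <- ctcfBoundaryFilter(seg, ctcf)
  before <- mean(cand %in% truthB)
  after <- mean(boundaryBins(filt) %in% truthB)
  expect_gt(after, before)
  expect_true(all(truthB %in% boundaryBins(filt)))
})

test_that("1-D Wasserstein distance has its closed-form values", {
  expect_equal(wasserstein1(10, 30), 20)
  expect_equal(wasserstein1(c(2, 4, 8), c(2, 4, 8)), 0)
  expect_equal(wasserstein1(c(1, 3), c(5, 9)), wasserstein1(c(5, 9), c(1, 3)))
  # against the quantile-coupling oracle on random samples
  withr::with_seed(4, {
    for (i in 1:10) {
      a <- sample(5:60, 30, replace = TRUE)
      b <- sample(5:80, 45, replace = TRUE)
      expect_equal(wasserstein1(a, b), oracleW1(a, b), tolerance = 1e-2)
    }
  })
})

test_that("mean dissimilarity skips empty chromosomes and averages W1", {
  gen <- list(c(10, 20), numeric(), c(5, 5))
  ref <- list(c(10, 22), c(1, 2), c(6, 6))
  expect_message(D <- wassersteinDissimilarity(gen, ref), "skipping")
  expect_equal(D, (wasserstein1(c(10, 20), c(10, 22)) +
                     wasserstein1(c(5, 5), c(6, 6))) / 2)
  expect_error(wassersteinDissimilarity(list(numeric()), list(1)),
               "non-empty")
})

test_that("size selection is self-consistent on its own segmentations", {
  withr::with_seed(7, {
    embs <- lapply(1:4, function(i) matrix(rnorm(200 * 4), 200, 4))
  })
  s <- 25L
  refs <- lapply(embs, function(z)
    as.numeric(segmentSizes(constrainedSegmentation(z, 200 %/% s,
                                                    pcaDims = 4))))
  res <- selectTldSize(embs, refs, candidates = 5:60, seed = 2,
                       pcaDims = 4)
  # the reference is reproduced exactly at s (D = 0); any candidate that
  # floors to the same cluster count ties, and ties break to the smaller
  expect_equal(res$dissimilarity[res$candidates == s], 0)
  zero <- res$candidates[res$dissimilarity == 0]
  expect_equal(res$optimum, min(zero))
  expect_true(all(res$dissimilarity >= res$dissimilarity[
    res$candidates == res$optimum]))
})

test_that("TLD size filter applies the 100 kb - 1 Mb window", {
  seg <- SegmentationResult(sizes = c(5L, 80L, 150L, 9L, 56L), nBins = 300L)
  expect_equal(tldSizeFilter(seg), c(80L, 56L))  # 90 kb and 50 kb fall out
})

test_that("consensus of identical segmentations reproduces them exactly", {
  seg <- SegmentationResult(sizes = c(8L, 12L, 10L, 10L), nBins = 40L)
  segs <- lapply(1:6, function(i) seg)
  C <- coAssociation(segs)
  expect_true(all(diag(C) == 1))
  expect_true(all(C >= 0 & C <= 1))
  blocks <- rep(1:4, c(8, 12, 10, 10))
  expect_equal(C, outer(blocks, blocks, function(a, b) (a == b) * 1))
  cons <- consensusTlds(segs, nClusters = 4L)
  expect_identical(segmentSizes(cons), segmentSizes(seg))
})

test_that("consensus boundaries come from the union of subpopulation truths", {
  trA <- simulateTruth(300, nLoops = 5, meanDomainSize = 20, seed = 51)
  trB <- simulateTruth(300, nLoops = 5, meanDomainSize = 25, seed = 52)
  mkSegs <- function(tr, m, seedBase) lapply(seq_len(m), function(i) {
    # per-cell segmentations: truth boundaries with light per-cell noise
    b <- truthBoundaries(tr)
    keep <- withr::with_seed(seedBase + i, runif(length(b)) < 0.9)
    SegmentationResult(boundaries = b[keep], nBins = 300L,
                       cellId = sprintf("s%d_%d", seedBase, i))
  })
  segs <- c(mkSegs(trA, 10, 100), mkSegs(trB, 10, 200))
  ncl <- length(truthBoundaries(trA)) + 1L
  cons <- consensusTlds(segs, nClusters = ncl)
  unionB <- sort(unique(c(truthBoundaries(trA), truthBoundaries(trB))))
  dists <- vapply(boundaryBins(cons), function(b) min(abs(unionB - b)),
                  numeric(1))
  expect_true(all(dists <= 1))
})

test_that("constrained segmentation scales near-quadratically", {
  ns <- c(250L, 500L, 1000L, 2000L)
  times <- vapply(ns, function(n) {
    z <- withr::with_seed(n, matrix(rnorm(n * 4), n, 4))
    # median of 3 runs stabilizes the small-n timings
    median(vapply(1:3, function(i)
      system.time(scArch:::segmentByWard(z, n %/% 20L))["elapsed"],
      numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(pmax(times, 1e-4)) ~ log(ns)))[2]
  expect_lte(slope, 2.4)
})
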