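test_that("latent feature pooling has the declared dimensionality and scaling", {
  n <- 47L  # deliberately not a multiple of 10
  g <- ContactGraph(u = 0:(n - 2), v = 1:(n - 1), w = rep(1, n - 1),
                    nBins = n)
  withr::with_seed(2, z <- matrix(rnorm(n * 8), n, 8))
  f <- encodeLatentFeatures(list(z), list(g))
  expect_equal(ncol(f), ceiling(n / 10))  # D = number of 100 kb bins
  # constant embedding -> PC1 constant -> equal pooled entries per window
  zc <- matrix(1, n, 8) + matrix(rep(rnorm(8), each = n), n, 8) * 0
  fc <- encodeLatentFeatures(list(zc), list(g))
  expect_lt(diff(range(fc[1, 1:4])), 1e-9)  # full windows equal
  # pooling linearity: scaling embeddings scales features
  f2 <- encodeLatentFeatures(list(2 * z), list(g))
  expect_equal(abs(f2), abs(2 * f), tolerance = 1e-9)
})

test_that("architectural features encode loops, boundaries and compartments", {
  # one loop (bins 10, 55) -> 100 kb bins 1 and 5 get +1
  loops <- list(data.frame(chrom = "chr1", u = 10L, v = 55L))
  f <- encodeArchitecturalFeatures("loop", loops, nBins = 80L)
  expect_equal(as.vector(f), c(0, 1, 0, 0, 0, 1, 0, 0))
  # no boundaries -> all-zero TLD vector
  seg <- SegmentationResult(sizes = 80L, nBins = 80L)
  ft <- encodeArchitecturalFeatures("tld", list(seg))
  expect_true(all(ft == 0))
  segB <- SegmentationResult(boundaries = c(25L, 60L), nBins = 80L)
  ftB <- encodeArchitecturalFeatures("tld", list(segB))
  expect_equal(as.vector(ftB), c(0, 0, 1, 0, 0, 0, 1, 0))
  # constant compartment scores coarsen to the same constant
  trk <- methods::new("CompartmentTrack", chrom = "chr1", cellId = "c",
                      score = rep(0.3, 80))
  fcmp <- encodeArchitecturalFeatures("compartment", list(trk))
  expect_equal(as.vector(fcmp), rep(0.3, 8), tolerance = 1e-12)
})

test_that("the four 100 kb feature kinds share one dimensionality", {
  n <- 120L
  g <- ContactGraph(u = 0:(n - 2), v = 1:(n - 1), w = rep(1, n - 1),
                    nBins = n)
  withr::with_seed(4, z <- matrix(rnorm(n * 6), n, 6))
  seg <- SegmentationResult(boundaries = c(30L, 70L), nBins = n)
  trk <- methods::new("CompartmentTrack", chrom = "chr1", cellId = "c",
                      score = rep(0, n))
  d <- c(ncol(encodeLatentFeatures(list(z), list(g))),
         ncol(encodeArchitecturalFeatures("loop",
           list(data.frame(u = 10L, v = 30L)), nBins = n)),
         ncol(encodeArchitecturalFeatures("tld", list(seg))),
         ncol(encodeArchitecturalFeatures("compartment", list(trk))))
  expect_equal(length(unique(d)), 1L)
})

test_that("tf-idf matches the hand computation and normalizes rows", {
  AC <- matrix(c(2, 0), 2, 1, dimnames = list(NULL, "chr1:5"))
  enc <- tfidfEncode(cbind(AC, other = c(1, 1)))
  idfExpected <- log(3 / 2) + 1
  expect_equal(enc$idf[["chr1:5"]], idfExpected)
  # pre-normalization value 2 * idf; check via the ratio to the other column
  expect_equal(unname(enc$tfidf[1, "chr1:5"] / enc$tfidf[1, "other"]),
               2 * idfExpected / (log(3 / 3) + 1))
  nrm <- sqrt(rowSums(enc$tfidf^2))
  expect_equal(nrm, c(1, 1), tolerance = 1e-9)
  # anchor present everywhere with equal counts -> equal values
  AC2 <- matrix(c(3, 3, 3), 3, 1, dimnames = list(NULL, "a"))
  expect_warning(enc2 <- tfidfEncode(cbind(AC2 * 0)), "zero loops")
  enc3 <- tfidfEncode(AC2)
  expect_equal(diff(range(enc3$tfidf)), 0)
})

test_that("anchor counts register both anchors of every loop", {
  calls <- list(data.frame(chrom = "chr1", u = c(3L, 3L), v = c(20L, 30L)),
                data.frame(chrom = "chr1", u = 20L, v = 40L))
  AC <- anchorCountMatrix(calls)
  expect_equal(unname(AC[1, "chr1:3"]), 2L)
  expect_equal(unname(AC[1, "chr1:20"]), 1L)
  expect_equal(unname(AC[2, "chr1:20"]), 1L)
  expect_equal(sum(AC), 6L)  # 3 loops x 2 anchors
})

test_that("classification separates separable features and fails null labels", {
  withr::with_seed(11, {
    n <- 40L
    labels <- rep(c("x", "y"), each = n / 2)
    X <- matrix(rnorm(n * 10, sd = 0.2), n, 10)
    X[labels == "x", 1] <- X[labels == "x", 1] + 4  # orthogonal signature
    X[labels == "y", 2] <- X[labels == "y", 2] + 4
  })
  res <- embedAndClassify(X, labels, trainFrac = 0.75, seed = 2)
  expect_equal(res$accuracy, 1.0)
  expect_equal(dim(res$embedding2d), c(n, 2L))
  expect_equal(sum(res$confusion), length(res$testIdx))
  # permuted labels -> accuracy near the majority-class frequency
  withr::with_seed(12, permLab <- sample(labels))
  resP <- embedAndClassify(X, permLab, trainFrac = 0.75, seed = 2)
  p0 <- max(table(permLab)) / n
  expect_lt(abs(resP$accuracy - p0), 3 * sqrt(p0 * (1 - p0) / 10) + 0.25)
})

test_that("stratified splitting guards degenerate classes", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(embedAndClassify(X, c(rep("a", 9), "b"), seed = 1),
               "< 2 cells")
})

test_that("marker tables carry sane fold changes and order", {
  truths <- simulateTruthFamily(400, 2, nShared = 10, nExclusive = 6,
                                markerAnchors = 3L, seed = 71)
  cellTypes <- rep(c("type1", "type2"), each = 25)
  calls <- simulateLoopCalls(truths, cellTypes, detectProb = 0.7,
                             nBackground = 10, seed = 72)
  AC <- anchorCountMatrix(calls)
  tab <- suppressWarnings(discoverMarkerAnchors(AC, cellTypes, topK = 20))
  expect_true(all(tab$adjustedP >= 0 & tab$adjustedP <= 1))
  expect_true(!is.unsorted(tab$adjustedP))
  # an anchor with equal in/out means has zero log fold change
  AC2 <- cbind(AC, fake = 2L)
  tab2 <- suppressWarnings(discoverMarkerAnchors(AC2, cellTypes,
                                                 topK = 20))
  if ("fake" %in% tab2$anchor)
    expect_equal(tab2$logFoldChange[tab2$anchor == "fake"], c(0, 0),
                 tolerance = 1e-6)
  # planted hub anchors rank at the top for their own type
  hubs <- attr(truths, "markerAnchors")
  top1 <- tab[tab$cellType == "type1" & tab$adjustedP < 0.05, ]
  expect_gte(mean(paste0("chrS:", hubs[[1]]) %in% top1$anchor), 0.9)
})

test_that("L1-SVM feature ranking agrees with an independent sparse model", {
  # cross-check: on separable data, the anchors the L1 squared-hinge SVM
  # ranks top should also be selected by lasso-penalized logistic
  # regression (glmnet), an independent solver of a related objective
  withr::with_seed(31, {
    n <- 60L
    X <- matrix(abs(rnorm(n * 30, sd = 0.3)), n, 30)
    y <- rep(c(1, -1), each = n / 2)
    X[y == 1, 1:5] <- X[y == 1, 1:5] + 1.5  # informative block
  })
  fit <- scArch:::l1svmFit(X, y, C = 1)
  topSvm <- order(fit$w, decreasing = TRUE)[1:5]
  gl <- glmnet::glmnet(X, factor(y), family = "binomial", alpha = 1,
                       lambda = 0.05)
  wGl <- as.numeric(stats::coef(gl))[-1]
  topGl <- order(wGl, decreasing = TRUE)[1:5]
  expect_gte(length(intersect(topSvm, topGl)), 4L)
  expect_setequal(sort(topSvm), 1:5)
})
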