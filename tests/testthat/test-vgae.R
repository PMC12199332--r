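tinyConfig <- function(F, ...)
  vgaeConfig(F, hiddenDim = 8L, latentDim = 4L, decoderDims = c(6L, 4L, 3L),
             ...)

test_that("encoder without edges depends only on self weights", {
  n <- 5L
  g <- ContactGraph(integer(), integer(), numeric(), nBins = n)
  X <- matrix(rep(c(1, 2, 3), each = n), n, 3)
  m <- newVGAE(tinyConfig(3L), seed = 2)
  emb <- encodeGraph(m, g, X)
  # isolated nodes with equal features -> equal mu rows
  expect_equal(emb@mu[1, ], emb@mu[4, ], tolerance = 1e-12)
  expect_equal(emb@z, emb@mu)  # eval mode: z = mu
})

test_that("encoder is equivariant under node permutation", {
  withr::with_seed(5, {
    n <- 12L
    u <- sample(0:(n - 2), 15, replace = TRUE)
    v <- pmin(u + sample(1:4, 15, replace = TRUE), n - 1L)
    keep <- u < v
    g <- ContactGraph(u[keep], v[keep], rep(1, sum(keep)), nBins = n)
    X <- matrix(rnorm(n * 6), n, 6)
    perm <- sample(n)
  })
  m <- newVGAE(tinyConfig(6L), seed = 3)
  emb <- encodeGraph(m, g, X)
  e <- contactEdges(g)
  pu <- match(e$u + 1L, perm) - 1L; pv <- match(e$v + 1L, perm) - 1L
  gP <- ContactGraph(pu, pv, e$w, nBins = n)
  XP <- X
  XP[match(seq_len(n), perm), ] <- X
  embP <- encodeGraph(m, gP, XP)
  expect_equal(embP@mu[match(seq_len(n), perm), ], emb@mu,
               tolerance = 1e-5)
})

test_that("eval-mode encoding is deterministic and training mode samples", {
  tr <- smallTruth(40)
  g <- downsampleToCell(simulateBulkIntensity(tr), 120, seed = 1)
  gen <- simulateGenome(tr, seed = 2)
  X <- normalizeFeatures(buildNodeFeatures(gen, "chrS", k = 1))
  m <- newVGAE(tinyConfig(ncol(X)), seed = 4)
  e1 <- encodeGraph(m, g, X); e2 <- encodeGraph(m, g, X)
  expect_identical(e1@z, e2@z)
  t1 <- encodeGraph(m, g, X, mode = "train", seed = 9)
  t2 <- encodeGraph(m, g, X, mode = "train", seed = 9)
  expect_identical(t1@z, t2@z)
  expect_false(identical(t1@z, t1@mu))
})

test_that("decoder outputs calibrate and order-independence holds", {
  cfg <- tinyConfig(3L)
  m <- newVGAE(cfg, seed = 1)
  # zero out the final layers: sigmoid(0) = 0.5 whatever the input
  m@params$theta$W4 <- m@params$theta$W4 * 0
  m@params$theta$b4 <- 0
  z <- withr::with_seed(8, matrix(rnorm(40), 10, 4))
  pairs <- data.frame(u = c(0L, 2L, 4L), v = c(5L, 3L, 9L))
  p <- decodePairs(m, z, pairs, "loop")
  expect_equal(p, rep(0.5, 3), tolerance = 1e-12)
  # batch order does not matter
  m2 <- newVGAE(cfg, seed = 1)
  p1 <- decodePairs(m2, z, pairs, "loop")
  p2 <- decodePairs(m2, z, pairs[3:1, ], "loop")
  expect_equal(p1, rev(p2), tolerance = 1e-12)
  # concatenation decoding is directional; callers canonicalize u < v
  pSwap <- decodePairs(m2, z, data.frame(u = pairs$v, v = pairs$u), "loop")
  expect_false(isTRUE(all.equal(p1, pSwap, tolerance = 1e-9)))
})

test_that("loss components match their closed forms", {
  # posterior = prior
  expect_equal(klLoss(matrix(0, 3, 4), matrix(0, 3, 4)), 0)
  # single node, single dim, mu 1, log sigma 0 -> 1/2
  expect_equal(klLoss(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5,
               tolerance = 1e-9)
  # p = 0.5 everywhere -> BCE = ln 2
  expect_equal(bceLoss(rep(0.5, 8), rep(c(0, 1), 4)), log(2),
               tolerance = 1e-9)
  comp <- vgaeLoss(rep(0.5, 4), c(1, 0, 1, 0), rep(0.5, 2), c(1, 0),
                   matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(comp$total, 2 * log(2), tolerance = 1e-9)
  # KL non-negative for random parameters
  withr::with_seed(1, {
    for (i in 1:20)
      expect_gte(klLoss(matrix(rnorm(12), 3), matrix(rnorm(12), 3)), 0)
  })
})

test_that("backpropagation matches numerical gradients", {
  withr::with_seed(1, {
    g <- ContactGraph(u = c(0, 1, 2, 0), v = c(1, 2, 3, 3),
                      w = c(1, 1, 2, 1), nBins = 6)
    X <- matrix(rnorm(30), 6, 5)
  })
  cfg <- vgaeConfig(5L, hiddenDim = 7L, latentDim = 4L,
                    decoderDims = c(5L, 4L, 3L), dropout = 0)
  p <- scArch:::initParams(cfg, seed = 2)
  A <- scArch:::meanAdjacency(g)
  reconPairs <- data.frame(u = c(0, 1, 2), v = c(1, 2, 3))
  loopPairs <- data.frame(u = c(0, 0), v = c(3, 4))
  stepf <- function(pp) withr::with_seed(42,
    scArch:::graphStepR(pp, cfg, X, A, reconPairs, c(1, 1, 0),
                        loopPairs, c(1, 0), "train"))
  ana <- scArch:::flattenParams(stepf(p)$grads)
  fp <- scArch:::flattenParams(p)
  h <- 1e-6
  withr::with_seed(3, {
    for (nm in names(fp)) {
      for (i in sample(length(fp[[nm]]), min(2, length(fp[[nm]])))) {
        up <- fp; up[[nm]][i] <- up[[nm]][i] + h
        dn <- fp; dn[[nm]][i] <- dn[[nm]][i] - h
        num <- (stepf(scArch:::unflattenAssign(p, up))$loss$total -
                  stepf(scArch:::unflattenAssign(p, dn))$loss$total) / (2 * h)
        expect_equal(ana[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("compiled training step agrees with the R reference exactly", {
  withr::with_seed(4, {
    g <- ContactGraph(u = c(0, 1, 2, 0, 4), v = c(1, 2, 3, 3, 6),
                      w = rep(1, 5), nBins = 8)
    X <- matrix(rnorm(8 * 6), 8, 6)
  })
  cfg <- vgaeConfig(6L, hiddenDim = 9L, latentDim = 5L,
                    decoderDims = c(6L, 5L, 4L), dropout = 0.2)
  p <- scArch:::initParams(cfg, seed = 5)
  fp <- scArch:::flattenParams(p)
  A <- scArch:::meanAdjacency(g)
  reconPairs <- data.frame(u = c(0, 1, 2, 0), v = c(1, 2, 3, 3))
  loopPairs <- data.frame(u = c(0, 1), v = c(5, 7))
  rl <- c(1, 1, 0, 0); ll <- c(1, 0)
  rres <- withr::with_seed(42, scArch:::graphStepR(
    p, cfg, X, A, reconPairs, rl, loopPairs, ll, "train"))
  cres <- withr::with_seed(42, scArch:::graphStep(
    fp, cfg, X, A, reconPairs, rl, loopPairs, ll, "train"))
  expect_equal(unlist(rres$loss), unlist(cres$loss), tolerance = 1e-12)
  for (nm in names(rres$grads))
    expect_equal(unname(as.matrix(rres$grads[[nm]])),
                 unname(as.matrix(cres$grads[[nm]])), tolerance = 1e-10)
  # eval mode agrees too (no RNG consumed)
  rese <- scArch:::graphStepR(p, cfg, X, A, reconPairs, rl, loopPairs,
                              ll, "eval")
  cese <- scArch:::graphStep(fp, cfg, X, A, reconPairs, rl, loopPairs,
                             ll, "eval")
  expect_equal(unlist(rese$loss), unlist(cese$loss), tolerance = 1e-12)
})

test_that("negative sampling avoids positives and matches distances", {
  n <- 400L
  withr::with_seed(2, {
    pu <- sample(0:(n - 101L), 150)
    pos <- data.frame(u = pu, v = pu + sample(10:100, 150, TRUE))
    pos <- pos[!duplicated(paste(pos$u, pos$v)), ]
  })
  neg <- negativeSample(n, pos, nNeg = 10000L, band = c(10L, 100L),
                        seed = 5)
  expect_false(any(paste(neg$u, neg$v) %in% paste(pos$u, pos$v)))
  d <- neg$v - neg$u
  expect_true(all(d >= 10 & d <= 100))
  # distance distributions indistinguishable (chi-square on the support)
  posD <- table(factor(pos$v - pos$u, levels = 10:100))
  negD <- table(factor(d, levels = 10:100))
  keep <- posD > 0
  cs <- suppressWarnings(
    stats::chisq.test(negD[keep], p = posD[keep] / sum(posD)))
  expect_gt(cs$p.value, 0.01)
})

test_that("degenerate sampling universes are rejected", {
  # every band pair positive -> no negatives exist
  n <- 14L
  allPairs <- do.call(rbind, lapply(10:13, function(d)
    data.frame(u = 0:(n - 1 - d), v = d + 0:(n - 1 - d))))
  expect_error(negativeSample(n, allPairs, nNeg = 5L, band = c(10L, 13L),
                              seed = 1),
               "no negative pairs")
})

test_that("short training runs are reproducible and improve the loss", {
  tr <- simulateTruth(150, nLoops = 30, seed = 12)
  ds <- simulateDataset(5, list(tr), contactsPerCell = 600, seed = 13,
                        chrom = "chrA")
  trV <- simulateTruth(150, nLoops = 30, seed = 14)
  dsV <- simulateDataset(2, list(trV), contactsPerCell = 600, seed = 15,
                         chrom = "chrB")
  XA <- normalizeFeatures(buildNodeFeatures(ds$genome, "chrA", k = 2))
  XB <- normalizeFeatures(buildNodeFeatures(dsV$genome, "chrB", k = 2))
  refs <- rbind(data.frame(chrom = "chrA", u = tr@loops$u, v = tr@loops$v),
                data.frame(chrom = "chrB", u = trV@loops$u,
                           v = trV@loops$v))
  fb <- list(chrA = XA, chrB = XB)
  td <- prepareGraphData(ds$cells, fb, refs)
  vd <- prepareGraphData(dsV$cells, fb, refs)
  cfg <- vgaeConfig(ncol(XA), maxEpochs = 6L)
  m1 <- trainVGAE(td, vd, cfg, seed = 11)
  m2 <- trainVGAE(td, vd, cfg, seed = 11)
  expect_identical(m1@trainingLog, m2@trainingLog)
  expect_identical(m1@params, m2@params)
  # training loss improves over the short run
  ll <- m1@trainingLog$train
  expect_lt(ll[length(ll)], ll[1])
  expect_true(m1@trained)
})

test_that("checkpoints save and load losslessly", {
  cfg <- tinyConfig(4L)
  m <- newVGAE(cfg, seed = 6)
  m@trained <- TRUE
  f <- withr::local_tempfile()
  saveVGAE(m, f)
  m2 <- loadVGAE(f)
  expect_equal(m2@params, m@params, tolerance = 1e-12)
  expect_equal(m2@config, m@config)
})
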