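genHmmData <- function(Tn, means, sds, trans, seed) {
  withr::with_seed(seed, {
    s <- integer(Tn); s[1] <- 1L
    for (t in 2:Tn) s[t] <- sample(1:2, 1, prob = trans[s[t - 1], ])
    x <- cbind(rnorm(Tn, means[s, 1], sds), rnorm(Tn, means[s, 2], sds))
    list(x = x, states = s)
  })
}

test_that("Baum-Welch recovers well-separated HMM parameters", {
  means <- rbind(c(2, 0), c(-2, 1))
  trans <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  seqs <- lapply(1:5, function(i) genHmmData(300, means, 0.6, trans, i)$x)
  hmm <- fitCompartmentHMM(seqs, seed = 4)
  # match states by nearest mean, then require < 10% relative error
  m <- hmm@means
  ord <- if (sum((m[1, ] - means[1, ])^2) < sum((m[1, ] - means[2, ])^2))
    1:2 else 2:1
  for (k in 1:2)
    expect_lt(sqrt(sum((m[ord[k], ] - means[k, ])^2)) /
                sqrt(sum(means[k, ]^2)), 0.1)
  expect_equal(diag(hmm@transition[ord, ord]), c(0.95, 0.95),
               tolerance = 0.05, ignore_attr = TRUE)
  # log-likelihood trace is non-decreasing (EM guarantee)
  trace <- attr(hmm@logLik, "trace")
  expect_true(all(diff(trace) > -1e-6))
  # determinism
  hmm2 <- fitCompartmentHMM(seqs, seed = 4)
  expect_equal(hmm2@means, hmm@means, tolerance = 1e-12)
})

test_that("posteriors are normalized and the score maps them to [-1, 1]", {
  means <- rbind(c(1.5, 0), c(-1.5, 0))
  trans <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  d <- genHmmData(400, means, 0.7, trans, 9)
  hmm <- fitCompartmentHMM(list(d$x), seed = 2)
  gc <- ifelse(d$states == 1L, 0.55, 0.40) +
    withr::with_seed(3, rnorm(400, 0, 0.01))
  track <- callCompartments(hmm, d$x, gc)
  s <- compartmentScore(track)
  expect_true(all(abs(s) <= 1))
  # gamma(A) + gamma(B) = 1 within 1e-9 <=> |score| formulation consistent
  logB <- cbind(scArch:::logGaussDiag(d$x, hmm@means[1, ], hmm@vars[1, ]),
                scArch:::logGaussDiag(d$x, hmm@means[2, ], hmm@vars[2, ]))
  fb <- scArch:::forwardBackward(logB, log(hmm@initial),
                                 log(hmm@transition))
  expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
  # the signed score is the posterior difference: |score| = |2*gamma - 1|
  expect_equal(abs(s), abs(2 * fb$gamma[, 1] - 1), tolerance = 1e-9)
})

test_that("GC orientation makes the track immune to label switching", {
  means <- rbind(c(1.5, 0), c(-1.5, 0))
  trans <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  d <- genHmmData(300, means, 0.7, trans, 5)
  hmm <- fitCompartmentHMM(list(d$x), seed = 2)
  gc <- ifelse(d$states == 1L, 0.55, 0.40)
  t1 <- callCompartments(hmm, d$x, gc)
  flipped <- methods::new("CompartmentHMM",
                          means = hmm@means[2:1, ],
                          vars = hmm@vars[2:1, ],
                          transition = hmm@transition[2:1, 2:1],
                          initial = hmm@initial[2:1],
                          logLik = hmm@logLik)
  t2 <- callCompartments(flipped, d$x, gc)
  expect_equal(compartmentScore(t1), compartmentScore(t2),
               tolerance = 1e-9)
  # by construction of the flip: positive-score bins have the higher GC
  s <- compartmentScore(t1)
  expect_gte(mean(gc[s > 0]), mean(gc[s < 0]))
})

test_that("checkerboard synthetic data is recovered with >= 90% sign agreement", {
  tr <- simulateTruth(600, nLoops = 10, seed = 61)
  gen <- simulateGenome(tr, seed = 62)
  lab <- compartmentLabels(tr)
  # embeddings carrying compartment structure plus noise, as the encoder
  # produces on checkerboard maps
  z <- withr::with_seed(63,
    cbind(ifelse(lab == "A", 1.2, -1.2), 0) +
      matrix(rnorm(1200, 0, 0.8), 600, 2))
  hmm <- fitCompartmentHMM(list(z), seed = 64)
  track <- callCompartments(hmm, z, gen@gcByBin)
  agree <- mean((compartmentScore(track) > 0) == (lab == "A"))
  expect_gte(agree, 0.9)
})

test_that("consensus averaging is exact and contractive", {
  mk <- function(s) methods::new("CompartmentTrack", chrom = "chr1",
                                 cellId = "c", score = s)
  t1 <- mk(c(1, -1, 0.5)); t2 <- mk(c(-1, -1, 0.1))
  cons <- consensusCompartments(list(t1, t2))
  expect_equal(compartmentScore(cons), c(0, -1, 0.3))
  expect_equal(compartmentScore(consensusCompartments(list(t1))),
               compartmentScore(t1))
  # |consensus| never exceeds the max per-cell magnitude at a bin
  withr::with_seed(6, {
    tracks <- lapply(1:5, function(i) mk(runif(20, -1, 1)))
  })
  cons2 <- consensusCompartments(tracks)
  mags <- do.call(cbind, lapply(tracks, function(t) abs(compartmentScore(t))))
  expect_true(all(abs(compartmentScore(cons2)) <=
                    apply(mags, 1, max) + 1e-12))
})

test_that("GC ties fall back deterministically with a warning", {
  means <- rbind(c(2, 0), c(-2, 0))
  trans <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  d <- genHmmData(200, means, 0.5, trans, 8)
  hmm <- fitCompartmentHMM(list(d$x), seed = 3)
  gc <- rep(0.5, 200)
  expect_warning(t1 <- callCompartments(hmm, d$x, gc), "tie")
  expect_warning(t2 <- callCompartments(hmm, d$x, gc), "tie")
  expect_equal(compartmentScore(t1), compartmentScore(t2))
})
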