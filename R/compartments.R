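## A/B compartment calling: a two-state hidden Markov model with diagonal
## Gaussian emissions over (PCA-reduced) per-bin embeddings treated as a
## linear sequence along the genome. State identity is resolved by GC
## content (the higher-GC state is A and gets positive sign), which makes
## the signed track immune to HMM label switching.

logGaussDiag <- function(x, mean, var) {
  ## x: T x d matrix; returns T-vector of log densities
  d <- length(mean)
  -0.5 * (d * log(2 * pi) + sum(log(var)) +
            rowSums(sweep(x, 2, mean, "-")^2 / rep(var, each = nrow(x))))
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

## Scaled forward-backward for one sequence. Returns log-likelihood,
## posteriors gamma (T x 2) and pairwise xi sums (2 x 2).
forwardBackward <- function(logB, logPi, logT) {
  Tn <- nrow(logB)
  la <- matrix(-Inf, Tn, 2)  # log alpha
  la[1, ] <- logPi + logB[1, ]
  for (t in 2:Tn) {
    la[t, 1] <- logsumexp2(la[t - 1, 1] + logT[1, 1],
                           la[t - 1, 2] + logT[2, 1]) + logB[t, 1]
    la[t, 2] <- logsumexp2(la[t - 1, 1] + logT[1, 2],
                           la[t - 1, 2] + logT[2, 2]) + logB[t, 2]
  }
  ll <- logsumexp2(la[Tn, 1], la[Tn, 2])
  lb <- matrix(0, Tn, 2)     # log beta
  for (t in (Tn - 1):1) {
    lb[t, 1] <- logsumexp2(logT[1, 1] + logB[t + 1, 1] + lb[t + 1, 1],
                           logT[1, 2] + logB[t + 1, 2] + lb[t + 1, 2])
    lb[t, 2] <- logsumexp2(logT[2, 1] + logB[t + 1, 1] + lb[t + 1, 1],
                           logT[2, 2] + logB[t + 1, 2] + lb[t + 1, 2])
  }
  lg <- la + lb - ll
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    v <- la[seq_len(Tn - 1), i] + logT[i, j] +
      logB[2:Tn, j] + lb[2:Tn, j] - ll
    xi[i, j] <- sum(exp(v))
  }
  list(ll = ll, gamma = gamma, xi = xi)
}

#' Fit the two-state compartment HMM by Baum-Welch EM
#'
#' Emission means are initialized by k-means (k = 2, seeded) on the
#' pooled observations; EM runs to convergence (log-likelihood tolerance
#' \code{tol}) or \code{maxIter} iterations. On numerical failure the
#' fit restarts once with jittered initialization, then aborts. When more
#' than \code{maxSequences} sequences are supplied a random subset (drawn
#' without replacement) of that many is used.
#'
#' @param sequences list of T x d embedding matrices (PCA-reduce first;
#'   see \code{\link{reduceEmbedding}}).
#' @param seed RNG seed (k-means init and sequence sampling).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param maxIter EM iteration cap (default 200).
#' @param maxSequences training-sample cap (default 100 chromosomes).
#' @return a \linkS4class{CompartmentHMM} with the per-iteration
#'   log-likelihood trace in the \code{"trace"} attribute of
#'   \code{@logLik}.
#' @export
fitCompartmentHMM <- function(sequences, seed = 1L, tol = 1e-4,
                              maxIter = 200L, maxSequences = 100L) {
  stopifnot(length(sequences) >= 1L)
  sequences <- lapply(sequences, as.matrix)
  if (length(sequences) > maxSequences)
    sequences <- withSeed(deriveSeed(seed, 77L),
                          sample(sequences, maxSequences))
  fitOnce <- function(jitterSd) {
    pooled <- do.call(rbind, sequences)
    km <- withSeed(seed, kmeans(pooled, centers = 2L, nstart = 5L))
    means <- km$centers
    if (jitterSd > 0)
      means <- means + withSeed(deriveSeed(seed, 13L),
                                matrix(rnorm(length(means), 0, jitterSd),
                                       nrow(means)))
    vars <- rbind(apply(pooled[km$cluster == 1, , drop = FALSE], 2, var),
                  apply(pooled[km$cluster == 2, , drop = FALSE], 2, var))
    vars[!is.finite(vars) | vars < 1e-6] <- 1e-6
    trans <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
    init <- c(0.5, 0.5)
    prevLL <- -Inf; trace <- numeric()
    for (it in seq_len(maxIter)) {
      gammaSum <- matrix(0, 2, 1); xiSum <- matrix(0, 2, 2)
      initSum <- c(0, 0); ll <- 0
      meanNum <- matrix(0, 2, ncol(means)); varNum <- matrix(0, 2, ncol(means))
      gammas <- vector("list", length(sequences))
      for (s in seq_along(sequences)) {
        x <- sequences[[s]]
        logB <- cbind(logGaussDiag(x, means[1, ], vars[1, ]),
                      logGaussDiag(x, means[2, ], vars[2, ]))
        fb <- forwardBackward(logB, log(init), log(trans))
        if (!is.finite(fb$ll)) return(NULL)
        ll <- ll + fb$ll
        gammas[[s]] <- fb$gamma
        initSum <- initSum + fb$gamma[1, ]
        xiSum <- xiSum + fb$xi
        gammaSum <- gammaSum + colSums(fb$gamma)
        meanNum <- meanNum + t(fb$gamma) %*% x
      }
      trace <- c(trace, ll)
      means <- meanNum / as.vector(gammaSum)
      for (k in 1:2) {
        num <- matrix(0, 1, ncol(means))
        for (s in seq_along(sequences)) {
          x <- sequences[[s]]
          num <- num + colSums(fb2 <- gammas[[s]][, k] *
                                 sweep(x, 2, means[k, ], "-")^2)
        }
        vars[k, ] <- pmax(num / gammaSum[k], 1e-6)
      }
      trans <- xiSum / rowSums(xiSum)
      init <- initSum / sum(initSum)
      init <- pmax(init, 1e-12); init <- init / sum(init)
      trans <- pmax(trans, 1e-12); trans <- trans / rowSums(trans)
      if (is.finite(prevLL) && ll - prevLL < tol && ll >= prevLL - 1e-8)
        break
      prevLL <- ll
    }
    if (anyNA(means) || anyNA(vars)) return(NULL)
    hmm <- methods::new("CompartmentHMM", means = means, vars = vars,
                        transition = trans, initial = init,
                        logLik = ll)
    attr(hmm@logLik, "trace") <- trace
    hmm
  }
  fit <- fitOnce(0)
  if (is.null(fit)) {
    warnf("EM failure; restarting once with jittered initialization")
    fit <- fitOnce(0.1)
    if (is.null(fit)) stopf("EM diverged twice; aborting")
  }
  fit
}

## Viterbi path (1/2 state indices) for one sequence.
viterbiPath <- function(hmm, x) {
  logB <- cbind(logGaussDiag(x, hmm@means[1, ], hmm@vars[1, ]),
                logGaussDiag(x, hmm@means[2, ], hmm@vars[2, ]))
  logT <- log(hmm@transition)
  Tn <- nrow(x)
  delta <- matrix(-Inf, Tn, 2); psi <- matrix(0L, Tn, 2)
  delta[1, ] <- log(hmm@initial) + logB[1, ]
  for (t in 2:Tn) for (j in 1:2) {
    cand <- delta[t - 1, ] + logT[, j]
    psi[t, j] <- which.max(cand)
    delta[t, j] <- cand[psi[t, j]] + logB[t, j]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Call a GC-oriented compartment track for one chromosome
#'
#' Computes forward-backward posteriors, identifies the A state as the
#' one whose Viterbi-assigned bins have the higher mean GC, and returns
#' the signed score \eqn{\gamma(A) - \gamma(B)} per bin (in [-1, 1],
#' positive = A). When the mean GC of the two states ties exactly, the
#' state with the higher mean in embedding dimension 1 becomes A (with a
#' warning).
#'
#' @param hmm a fitted \linkS4class{CompartmentHMM}.
#' @param z bin embedding matrix (same dims the HMM was fitted on).
#' @param gcByBin per-bin GC fraction.
#' @param chrom,cellId metadata.
#' @return a \linkS4class{CompartmentTrack}.
#' @export
callCompartments <- function(hmm, z, gcByBin, chrom = "chr1",
                             cellId = "cell") {
  z <- as.matrix(z)
  stopifnot(length(gcByBin) == nrow(z))
  logB <- cbind(logGaussDiag(z, hmm@means[1, ], hmm@vars[1, ]),
                logGaussDiag(z, hmm@means[2, ], hmm@vars[2, ]))
  fb <- forwardBackward(logB, log(hmm@initial), log(hmm@transition))
  path <- viterbiPath(hmm, z)
  gc1 <- mean(gcByBin[path == 1L]); gc2 <- mean(gcByBin[path == 2L])
  if (is.nan(gc1)) gc1 <- -Inf
  if (is.nan(gc2)) gc2 <- -Inf
  aState <- if (gc1 > gc2) 1L else if (gc2 > gc1) 2L else {
    warnf("state GC tie; orienting by mean of embedding dimension 1")
    if (hmm@means[1, 1] >= hmm@means[2, 1]) 1L else 2L
  }
  score <- fb$gamma[, aState] - fb$gamma[, 3L - aState]
  methods::new("CompartmentTrack", chrom = chrom, cellId = cellId,
               score = pmin(pmax(score, -1), 1))
}

#' Consensus compartment track
#'
#' Per-bin arithmetic mean of the GC-oriented per-cell scores.
#'
#' @param tracks list of \linkS4class{CompartmentTrack} on the same bins.
#' @return a consensus \linkS4class{CompartmentTrack}.
#' @export
consensusCompartments <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  n <- length(tracks[[1]]@score)
  stopifnot(all(vapply(tracks, function(t) length(t@score), integer(1)) == n))
  s <- rowMeans(do.call(cbind, lapply(tracks, compartmentScore)))
  methods::new("CompartmentTrack", chrom = tracks[[1]]@chrom,
               cellId = "consensus", score = s)
}
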