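## Multi-task variational graph autoencoder. GraphSAGE mean-aggregation
## encoder (F -> 128 ReLU -> 64 mu / 64 log-sigma heads); two dense edge
## decoders with identical architecture but separate weights (Phi:
## contact reconstruction, Theta: loop classification) on concatenated
## pair embeddings [z_u, z_v] (input 128 -> 96 -> 64 -> 16 -> 1, ReLU,
## dropout 0.2 after each hidden layer, sigmoid output). Trained with
## BCE(recon) + BCE(loop) + KL under Adam. All forward/backward passes
## are dense base-R linear algebra; adjacency is binarized and
## row-normalized for neighbour averaging.

#' Default VGAE configuration
#'
#' @param featureDim input feature dimensionality F.
#' @param hiddenDim,latentDim encoder dims (128 / 64).
#' @param decoderDims hidden widths of both edge decoders.
#' @param dropout dropout rate after each decoder hidden layer.
#' @param lr Adam learning rate. @param weightDecay L2 coefficient added
#'   to gradients. @param patience early-stopping patience in epochs.
#' @param minDelta minimum validation-loss improvement counted as progress.
#' @param maxEpochs training epoch cap.
#' @param klWeight multiplier on the node-averaged KL term. The default
#'   NULL scales it by 1/N for a graph of N bins, following the
#'   reference VGAE implementations; pass a number to fix it.
#' @param negSampling "distance" (proximity-aware, matched to the positive
#'   distance distribution) or "uniform".
#' @param edgeBatch reconstruction-edge minibatch size per optimizer
#'   step; each graph pass covers all edges in disjoint random chunks.
#' @return named list.
#' @export
vgaeConfig <- function(featureDim, hiddenDim = 128L, latentDim = 64L,
                       decoderDims = c(96L, 64L, 16L), dropout = 0.2,
                       lr = 2e-5, weightDecay = 1e-3, patience = 5L,
                       minDelta = 1e-6, maxEpochs = 100L, klWeight = NULL,
                       negSampling = c("distance", "uniform"),
                       edgeBatch = 1024L) {
  list(featureDim = as.integer(featureDim), hiddenDim = as.integer(hiddenDim),
       latentDim = as.integer(latentDim), decoderDims = as.integer(decoderDims),
       dropout = dropout, lr = lr, weightDecay = weightDecay,
       patience = as.integer(patience), minDelta = minDelta,
       maxEpochs = as.integer(maxEpochs),
       klWeight = if (is.null(klWeight)) NA_real_ else klWeight,
       negSampling = match.arg(negSampling),
       edgeBatch = as.integer(edgeBatch))
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

initParams <- function(config, seed = 1L) {
  withSeed(seed, {
    F <- config$featureDim; H <- config$hiddenDim; D <- config$latentDim
    dd <- c(2L * D, config$decoderDims, 1L)
    mkDec <- function() {
      dec <- list()
      for (i in seq_len(length(dd) - 1L)) {
        dec[[paste0("W", i)]] <- glorot(dd[i], dd[i + 1L])
        dec[[paste0("b", i)]] <- numeric(dd[i + 1L])
      }
      dec
    }
    list(enc1Ws = glorot(F, H), enc1Wn = glorot(F, H), enc1b = numeric(H),
         muWs = glorot(H, D), muWn = glorot(H, D), mub = numeric(D),
         lsWs = glorot(H, D), lsWn = glorot(H, D), lsb = numeric(D),
         phi = mkDec(), theta = mkDec())
  })
}

#' Create an (untrained) VGAE model
#' @param config from \code{\link{vgaeConfig}}.
#' @param seed weight initialization seed.
#' @return a \linkS4class{VGAEModel}.
#' @export
newVGAE <- function(config, seed = 1L) {
  methods::new("VGAEModel", params = initParams(config, seed),
               config = config, trained = FALSE,
               trainingLog = data.frame())
}

## Row-normalized binarized adjacency (mean aggregation operator).
## Isolated nodes get an all-zero row (neighbour term vanishes).
meanAdjacency <- function(graph) {
  e <- graph@edges
  e <- e[e$u != e$v, , drop = FALSE]
  n <- graph@nBins
  if (nrow(e) == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  i <- c(e$u, e$v) + 1L; j <- c(e$v, e$u) + 1L
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                            use.last.ij = TRUE)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% A
}

relu <- function(x) pmax(x, 0)

addBias <- function(M, b) M + rep(b, each = nrow(M))

encForward <- function(params, X, A, mode = "eval", eps = NULL,
                       AX = NULL) {
  if (is.null(AX)) AX <- as.matrix(A %*% X)
  H1pre <- addBias(X %*% params$enc1Ws + AX %*% params$enc1Wn,
                   params$enc1b)
  H1 <- relu(H1pre)
  AH1 <- as.matrix(A %*% H1)
  Mu <- addBias(H1 %*% params$muWs + AH1 %*% params$muWn, params$mub)
  LS <- addBias(H1 %*% params$lsWs + AH1 %*% params$lsWn, params$lsb)
  if (anyNA(Mu) || anyNA(LS) || any(!is.finite(Mu)) || any(!is.finite(LS)))
    stopf("NaN/Inf in encoder activations; aborting")
  if (mode == "train") {
    if (is.null(eps)) eps <- matrix(rnorm(length(Mu)), nrow(Mu), ncol(Mu))
    Z <- Mu + exp(LS) * eps
  } else {
    eps <- NULL
    Z <- Mu
  }
  list(X = X, AX = AX, H1pre = H1pre, H1 = H1, AH1 = AH1,
       Mu = Mu, LS = LS, eps = eps, Z = Z)
}

mlpForward <- function(dec, In, mode, dropout) {
  nH <- (length(dec) %/% 2L) - 1L
  acts <- vector("list", nH); pres <- vector("list", nH)
  masks <- vector("list", nH)
  cur <- In
  for (i in seq_len(nH)) {
    pre <- addBias(cur %*% dec[[paste0("W", i)]], dec[[paste0("b", i)]])
    act <- relu(pre)
    if (mode == "train" && dropout > 0) {
      m <- matrix(runif(length(act)) >= dropout, nrow(act), ncol(act))
      act <- act * m / (1 - dropout)
      masks[[i]] <- m
    }
    pres[[i]] <- pre; acts[[i]] <- act
    cur <- act
  }
  iF <- nH + 1L
  logit <- addBias(cur %*% dec[[paste0("W", iF)]], dec[[paste0("b", iF)]])
  p <- 1 / (1 + exp(-logit))
  list(In = In, pres = pres, acts = acts, masks = masks,
       logit = logit, p = as.vector(p))
}

## Backprop through one decoder given dLoss/dlogit; returns grads and dIn.
mlpBackward <- function(dec, cache, dlogit, mode, dropout) {
  nH <- (length(dec) %/% 2L) - 1L
  grads <- list()
  iF <- nH + 1L
  last <- if (nH > 0) cache$acts[[nH]] else cache$In
  dlogit <- matrix(dlogit, ncol = 1L)
  grads[[paste0("W", iF)]] <- crossprod(last, dlogit)
  grads[[paste0("b", iF)]] <- colSums(dlogit)
  dcur <- dlogit %*% t(dec[[paste0("W", iF)]])
  for (i in rev(seq_len(nH))) {
    if (mode == "train" && dropout > 0)
      dcur <- dcur * cache$masks[[i]] / (1 - dropout)
    dpre <- dcur * (cache$pres[[i]] > 0)
    below <- if (i > 1L) cache$acts[[i - 1L]] else cache$In
    grads[[paste0("W", i)]] <- crossprod(below, dpre)
    grads[[paste0("b", i)]] <- colSums(dpre)
    dcur <- dpre %*% t(dec[[paste0("W", i)]])
  }
  list(grads = grads, dIn = dcur)
}

clipProb <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Binary cross-entropy (mean), with probability clipping
#' @param p predicted probabilities; @param y 0/1 labels.
#' @export
bceLoss <- function(p, y) {
  p <- clipProb(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' KL divergence of the latent posterior from the standard normal prior
#'
#' Per-node average: \eqn{(1/N) \sum_u -\tfrac12 \sum_d (1 + 2\log\sigma -
#' \mu^2 - \sigma^2)}. Always >= 0.
#'
#' @param mu,logSigma N x D matrices.
#' @export
klLoss <- function(mu, logSigma) {
  -0.5 * sum(1 + 2 * logSigma - mu^2 - exp(2 * logSigma)) / nrow(mu)
}

#' Total multi-task VGAE loss and its components
#'
#' @param reconProbs,reconLabels reconstruction-task probabilities/labels.
#' @param loopProbs,loopLabels loop-task probabilities/labels.
#' @param mu,logSigma encoder outputs.
#' @param klWeight multiplier on the KL term.
#' @return list(total, bceRecon, bceLoop, kl).
#' @export
vgaeLoss <- function(reconProbs, reconLabels, loopProbs, loopLabels,
                     mu, logSigma, klWeight = 1) {
  br <- bceLoss(reconProbs, reconLabels)
  bl <- bceLoss(loopProbs, loopLabels)
  kl <- klLoss(mu, logSigma)
  list(total = br + bl + klWeight * kl, bceRecon = br, bceLoop = bl, kl = kl)
}

#' Proximity-aware negative pair sampling
#'
#' Draws \code{nNeg} non-positive bin pairs. With
#' \code{method = "distance"} the genomic-distance distribution of the
#' negatives is matched to the positives: each negative's separation is
#' drawn from the empirical positive-distance histogram, then a uniform
#' non-positive pair at that separation is chosen (falling back to the
#' nearest feasible separation when a distance stratum is exhausted).
#' With \code{"uniform"}, separations are uniform over the allowed range.
#'
#' @param nBins chromosome length in bins.
#' @param positives data.frame(u, v) with u < v.
#' @param nNeg number of negatives (defaults to nrow(positives)).
#' @param band optional c(minBins, maxBins) separation bounds (loop task).
#' @param seed RNG seed.
#' @param method "distance" or "uniform".
#' @param cache optional environment reused across calls to memoize the
#'   per-distance eligible-pair lists (they depend only on the positive
#'   set, which is fixed during training).
#' @return data.frame(u, v).
#' @export
negativeSample <- function(nBins, positives, nNeg = nrow(positives),
                           band = NULL, seed = 1L,
                           method = c("distance", "uniform"),
                           cache = NULL) {
  method <- match.arg(method)
  posKey <- sort(pairKey(positives$u, positives$v, nBins))
  dmin <- if (is.null(band)) 1L else band[1]
  dmax <- if (is.null(band)) nBins - 1L else min(band[2], nBins - 1L)
  freeAt <- function(d) {
    us <- 0:(nBins - 1L - d)
    keys <- pairKey(us, us + d, nBins)
    us[!(keys %in% posKey)]
  }
  withSeed(seed, {
    posD <- positives$v - positives$u
    wantD <- if (method == "distance")
      sample(posD, nNeg, replace = TRUE)
    else sample(seq(dmin, dmax), nNeg, replace = TRUE)
    tab <- table(wantD)
    out <- vector("list", length(tab))
    freeCache <- if (is.null(cache)) new.env(parent = emptyenv()) else cache
    getFree <- function(d) {
      key <- as.character(d)
      if (is.null(freeCache[[key]])) freeCache[[key]] <- freeAt(d)
      freeCache[[key]]
    }
    for (i in seq_along(tab)) {
      d <- as.integer(names(tab)[i]); m <- as.integer(tab[i])
      free <- getFree(d)
      if (length(free) == 0L) {
        found <- FALSE
        for (off in seq_len(dmax - dmin)) {
          for (dd in c(d - off, d + off)) {
            if (dd < dmin || dd > dmax) next
            free <- getFree(dd)
            if (length(free)) { d <- dd; found <- TRUE; break }
          }
          if (found) break
        }
        if (!found) stopf("no negative pairs available in the band")
        message(sprintf("negativeSample: distance %s exhausted, using %d",
                        names(tab)[i], d))
      }
      us <- free[sample.int(length(free), m, replace = TRUE)]
      out[[i]] <- data.frame(u = us, v = us + d)
    }
    do.call(rbind, out)
  })
}

#' Encode a contact graph into per-bin latent distributions
#'
#' @param model a \linkS4class{VGAEModel}.
#' @param graph a \linkS4class{ContactGraph}.
#' @param X node feature matrix (already standardized), rows = bins.
#' @param mode "eval" (z = mu, deterministic) or "train" (reparameterized
#'   sample).
#' @param seed RNG seed used for the reparameterization draw in train mode.
#' @return a \linkS4class{LatentEmbedding}.
#' @export
encodeGraph <- function(model, graph, X, mode = c("eval", "train"),
                        seed = 1L) {
  mode <- match.arg(mode)
  if (methods::is(X, "NodeFeatureMatrix")) X <- X@values
  if (nrow(X) != graph@nBins)
    stopf("feature rows (%d) != graph bins (%d)", nrow(X), graph@nBins)
  A <- meanAdjacency(graph)
  fw <- if (mode == "train")
    withSeed(seed, encForward(model@params, X, A, "train"))
  else encForward(model@params, X, A, "eval")
  methods::new("LatentEmbedding", mu = fw$Mu, logSigma = fw$LS, z = fw$Z)
}

#' Decode pair probabilities from latent embeddings
#'
#' @param model a \linkS4class{VGAEModel}.
#' @param z N x D latent matrix (e.g. \code{emb@z}).
#' @param pairs data.frame(u, v), 0-based bins, canonical u < v.
#' @param decoder "loop" (Theta) or "recon" (Phi).
#' @return numeric probabilities in (0, 1).
#' @export
decodePairs <- function(model, z, pairs, decoder = c("loop", "recon")) {
  decoder <- match.arg(decoder)
  dec <- if (decoder == "loop") model@params$theta else model@params$phi
  In <- cbind(z[pairs$u + 1L, , drop = FALSE],
              z[pairs$v + 1L, , drop = FALSE])
  mlpForward(dec, In, mode = "eval", dropout = 0)$p
}

## One graph's training step: forward, loss, full backward.
## Pure-R reference implementation; training uses the compiled
## equivalent (cppGraphStep) and the tests assert their agreement.
## Returns list(grads (flat named list), loss components).
graphStepR <- function(params, config, X, A, reconPairs, reconLab,
                      loopPairs, loopLab, mode = "train", AX = NULL) {
  fw <- encForward(params, X, A, mode, AX = AX)
  N <- nrow(X); D <- ncol(fw$Mu)
  mkIn <- function(pairs)
    cbind(fw$Z[pairs$u + 1L, , drop = FALSE],
          fw$Z[pairs$v + 1L, , drop = FALSE])
  cPhi <- mlpForward(params$phi, mkIn(reconPairs), mode, config$dropout)
  cTheta <- mlpForward(params$theta, mkIn(loopPairs), mode, config$dropout)
  klw <- effKlWeight(config, N)
  comp <- vgaeLoss(cPhi$p, reconLab, cTheta$p, loopLab, fw$Mu, fw$LS,
                   klw)
  if (mode != "train") return(list(grads = NULL, loss = comp))

  dZ <- matrix(0, N, D)
  accPairGrad <- function(pairs, dIn) {
    iu <- pairs$u + 1L; iv <- pairs$v + 1L
    gU <- rowsum(dIn[, seq_len(D), drop = FALSE], iu)
    gV <- rowsum(dIn[, D + seq_len(D), drop = FALSE], iv)
    dZ[as.integer(rownames(gU)), ] <<- dZ[as.integer(rownames(gU)), ] + gU
    dZ[as.integer(rownames(gV)), ] <<- dZ[as.integer(rownames(gV)), ] + gV
  }
  dlogitPhi <- (clipProb(cPhi$p) - reconLab) / length(reconLab)
  bwPhi <- mlpBackward(params$phi, cPhi, dlogitPhi, mode, config$dropout)
  accPairGrad(reconPairs, bwPhi$dIn)
  dlogitTheta <- (clipProb(cTheta$p) - loopLab) / length(loopLab)
  bwTheta <- mlpBackward(params$theta, cTheta, dlogitTheta, mode,
                         config$dropout)
  accPairGrad(loopPairs, bwTheta$dIn)

  dMu <- dZ + klw * fw$Mu / N
  dLS <- dZ * fw$eps * exp(fw$LS) + klw * (exp(2 * fw$LS) - 1) / N

  g <- list()
  g$muWs <- crossprod(fw$H1, dMu); g$muWn <- crossprod(fw$AH1, dMu)
  g$mub <- colSums(dMu)
  g$lsWs <- crossprod(fw$H1, dLS); g$lsWn <- crossprod(fw$AH1, dLS)
  g$lsb <- colSums(dLS)
  dH1 <- dMu %*% t(params$muWs) + as.matrix(Matrix::crossprod(A, dMu)) %*%
    t(params$muWn) +
    dLS %*% t(params$lsWs) + as.matrix(Matrix::crossprod(A, dLS)) %*%
    t(params$lsWn)
  dpre1 <- dH1 * (fw$H1pre > 0)
  g$enc1Ws <- crossprod(fw$X, dpre1); g$enc1Wn <- crossprod(fw$AX, dpre1)
  g$enc1b <- colSums(dpre1)
  g$phi <- bwPhi$grads; g$theta <- bwTheta$grads
  list(grads = flattenParams(g), loss = comp)
}

## Effective KL weight for a graph of N bins: the configured value, or
## the reference-implementation default 1/N.
effKlWeight <- function(config, n) {
  if (is.na(config$klWeight)) 1 / n else config$klWeight
}

## Compiled step on the concatenated parameter vector; same RNG
## consumption order as graphStepR, so seeded runs agree between paths.
cppStep <- function(wvec, lay, config, X, A, reconPairs, reconLab,
                    loopPairs, loopLab, mode = "train", AX = NULL) {
  if (is.null(AX)) AX <- as.matrix(A %*% X)
  cppGraphStepVec(wvec, lay$names, lay$offs, lay$nrows, lay$ncols,
                  X, methods::as(A, "CsparseMatrix"), AX,
                  reconPairs$u, reconPairs$v, as.numeric(reconLab),
                  loopPairs$u, loopPairs$v, as.numeric(loopLab),
                  config$dropout, effKlWeight(config, nrow(X)),
                  mode == "train", length(config$decoderDims))
}

## Convenience wrapper over cppStep taking a flat parameter list
## (used by the R-vs-compiled agreement tests).
graphStep <- function(flat, config, X, A, reconPairs, reconLab,
                      loopPairs, loopLab, mode = "train", AX = NULL) {
  lay <- adamLayout(flat)
  res <- cppStep(flatToVec(flat, lay), lay, config, X, A, reconPairs,
                 reconLab, loopPairs, loopLab, mode, AX)
  if (!is.null(res$grads)) res$grads <- vecToFlat(res$grads, lay)
  res
}

## Flatten nested param/grad lists for the optimizer.
flattenParams <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]]))
      out <- c(out, flattenParams(p[[nm]], paste0(prefix, nm, ".")))
    else out[[paste0(prefix, nm)]] <- p[[nm]]
  }
  out
}

unflattenAssign <- function(params, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) params[[parts]] <- flat[[nm]]
    else params[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  params
}

adamInit <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

## Vectorized Adam over one concatenated parameter vector. `lay` caches
## the flat-list layout (names, lengths, dims) so the list form can be
## rebuilt cheaply after each step.
adamLayout <- function(flat) {
  lens <- vapply(flat, length, integer(1))
  dims <- lapply(flat, dim)
  list(names = names(flat), lens = lens, dims = dims,
       offs = c(0L, cumsum(lens))[seq_along(lens)],
       nrows = vapply(seq_along(flat), function(j)
         if (is.null(dims[[j]])) lens[[j]] else dims[[j]][1], integer(1)),
       ncols = vapply(seq_along(flat), function(j)
         if (is.null(dims[[j]])) 0L else dims[[j]][2], integer(1)))
}

flatToVec <- function(flat, lay) unlist(flat[lay$names], use.names = FALSE)

vecToFlat <- function(vec, lay) {
  out <- vector("list", length(lay$names))
  names(out) <- lay$names
  off <- 0L
  for (j in seq_along(out)) {
    vals <- vec[(off + 1L):(off + lay$lens[j])]
    d <- lay$dims[[j]]
    out[[j]] <- if (is.null(d)) vals else matrix(vals, d[1], d[2])
    off <- off + lay$lens[j]
  }
  out
}

adamUpdateVec <- function(w, g, state, lr, weightDecay,
                          beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  state$t <- state$t + 1L
  g <- g + weightDecay * w
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(w = w - lr * mhat / (sqrt(vhat) + epsilon), state = state)
}

adamUpdate <- function(flat, grads, state, lr, weightDecay,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]] + weightDecay * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + epsilon)
  }
  list(flat = flat, state = state)
}

#' Assemble per-graph training data
#'
#' Pairs each contact graph with its (standardized) node features and the
#' reference loop positives falling in the 100 kb - 1 Mb band. A graph's
#' loop positives are the reference pairs in the band regardless of
#' whether the individual cell's sparse map has a contact there (labels
#' are population-level).
#'
#' @param graphs list of \linkS4class{ContactGraph}.
#' @param featuresByChrom named list (chrom -> standardized feature
#'   matrix).
#' @param referenceLoops data.frame(chrom, u, v).
#' @return list of list(graph, X, A, reconPos, loopPos).
#' @export
prepareGraphData <- function(graphs, featuresByChrom, referenceLoops) {
  lapply(graphs, function(g) {
    X <- featuresByChrom[[chrom(g)]]
    if (is.null(X)) stopf("no features for chromosome %s", chrom(g))
    if (methods::is(X, "NodeFeatureMatrix")) X <- X@values
    ref <- referenceLoops[referenceLoops$chrom == chrom(g), , drop = FALSE]
    band <- inLoopBand(ref$u, ref$v, g@resolution)
    loopPos <- data.frame(u = pmin(ref$u, ref$v)[band],
                          v = pmax(ref$u, ref$v)[band])
    loopPos <- loopPos[loopPos$v < g@nBins, , drop = FALSE]
    e <- g@edges[g@edges$u != g@edges$v, , drop = FALSE]
    A <- meanAdjacency(g)
    list(graph = g, X = X, A = A, AX = as.matrix(A %*% X),
         reconPos = data.frame(u = e$u, v = e$v), loopPos = loopPos,
         reconCache = new.env(parent = emptyenv()),
         loopCache = new.env(parent = emptyenv()))
  })
}

## Assemble one graph's positive/negative edge batches for both tasks.
graphBatches <- function(d, config, seedBase, i) {
  if (nrow(d$loopPos) == 0L) stopf("graph %d has no loop labels in band", i)
  negR <- negativeSample(d$graph@nBins, d$reconPos,
                         seed = deriveSeed(seedBase, 2L * i),
                         method = config$negSampling,
                         cache = d$reconCache)
  negL <- negativeSample(d$graph@nBins, d$loopPos,
                         band = c(LOOP_BAND_MIN_BINS, LOOP_BAND_MAX_BINS),
                         seed = deriveSeed(seedBase, 2L * i + 1L),
                         method = config$negSampling,
                         cache = d$loopCache)
  list(reconPairs = rbind(d$reconPos, negR),
       reconLab = rep(c(1, 0), c(nrow(d$reconPos), nrow(negR))),
       loopPairs = rbind(d$loopPos, negL),
       loopLab = rep(c(1, 0), c(nrow(d$loopPos), nrow(negL))))
}

## One full evaluation pass (no gradients, eval mode, z = mu).
evalLoss <- function(wvec, lay, config, data, seedBase) {
  tot <- c(total = 0, bceRecon = 0, bceLoop = 0, kl = 0)
  for (i in seq_along(data)) {
    d <- data[[i]]
    b <- graphBatches(d, config, seedBase, i)
    res <- cppStep(wvec, lay, config, d$X, d$A, b$reconPairs, b$reconLab,
                   b$loopPairs, b$loopLab, "eval", AX = d$AX)
    tot <- tot + unlist(res$loss) / length(data)
  }
  tot
}

#' Train the multi-task VGAE
#'
#' Mini-batched Adam: one (cell, chromosome) graph per optimizer step,
#' an epoch being a full pass over the training graphs. Per-epoch
#' validation loss is computed in eval mode with negatives re-sampled
#' from a fixed validation seed; training stops when the best validation
#' loss has not improved by at least \code{minDelta} for \code{patience}
#' consecutive epochs, and the best-validation checkpoint is returned.
#'
#' @param trainData,valData from \code{\link{prepareGraphData}}; the two
#'   sets must not share graphs (use disjoint chromosomes or cells).
#' @param config from \code{\link{vgaeConfig}}.
#' @param seed master seed (weights, negative sampling, dropout, eps).
#' @param verbose print per-epoch losses.
#' @return a trained \linkS4class{VGAEModel} with a per-epoch
#'   \code{trainingLog}.
#' @export
trainVGAE <- function(trainData, valData, config, seed = 1L,
                      verbose = FALSE) {
  if (!length(trainData) || !length(valData))
    stopf("need non-empty training and validation sets")
  params <- initParams(config, seed)
  flat <- flattenParams(params)
  lay <- adamLayout(flat)
  wvec <- flatToVec(flat, lay)
  state <- list(m = wvec * 0, v = wvec * 0, t = 0L)
  bestVal <- Inf; bestVec <- wvec; wait <- 0L
  log <- data.frame()
  valSeed <- deriveSeed(seed, 999983L)
  for (epoch in seq_len(config$maxEpochs)) {
    seedBase <- deriveSeed(seed, epoch)
    tot <- c(total = 0, bceRecon = 0, bceLoop = 0, kl = 0)
    for (i in seq_along(trainData)) {
      d <- trainData[[i]]
      b <- graphBatches(d, config, seedBase, i)
      nE <- nrow(d$reconPos)
      nChunks <- max(1L, ceiling(nE / config$edgeBatch))
      chunkOf <- withSeed(deriveSeed(seedBase, 5000L + i),
                          sample(rep_len(seq_len(nChunks), nE)))
      negChunkOf <- rep_len(seq_len(nChunks), nrow(b$reconPairs) - nE)
      stepLoss <- c(total = 0, bceRecon = 0, bceLoop = 0, kl = 0)
      for (ch in seq_len(nChunks)) {
        sel <- c(which(chunkOf == ch),
                 nE + which(negChunkOf == ch))
        res <- withSeed(deriveSeed(seedBase, 1000L + i * 37L + ch),
                        cppStep(wvec, lay, config, d$X, d$A,
                                b$reconPairs[sel, , drop = FALSE],
                                b$reconLab[sel],
                                b$loopPairs, b$loopLab, "train",
                                AX = d$AX))
        stepLoss <- stepLoss + unlist(res$loss) / nChunks
        state$t <- state$t + 1L
        upd <- cppAdamStep(wvec, res$grads, state$m, state$v, state$t,
                           config$lr, config$weightDecay)
        wvec <- upd$w; state$m <- upd$m; state$v <- upd$v
      }
      tot <- tot + stepLoss / length(trainData)
    }
    va <- evalLoss(wvec, lay, config, valData, valSeed)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train = tot["total"],
                                 trainRecon = tot["bceRecon"],
                                 trainLoop = tot["bceLoop"],
                                 trainKL = tot["kl"],
                                 val = va["total"],
                                 row.names = NULL))
    if (verbose)
      message(sprintf("epoch %3d train %.5f val %.5f", epoch,
                      tot["total"], va["total"]))
    if (va["total"] < bestVal - config$minDelta) {
      bestVal <- va["total"]; bestVec <- wvec; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  methods::new("VGAEModel",
               params = unflattenAssign(params, vecToFlat(bestVec, lay)),
               config = config, trained = TRUE, trainingLog = log)
}

#' Save / load a VGAE checkpoint as plain JSON-free text (RDS-less)
#'
#' Weights are serialized as a TSV-backed flat list via \code{dput} for
#' portability inside a text-only artifact.
#'
#' @param model a VGAEModel. @param path file path.
#' @export
saveVGAE <- function(model, path) {
  flat <- flattenParams(model@params)
  obj <- list(config = model@config, trained = model@trained,
              params = lapply(flat, function(m)
                list(dim = dim(m), values = as.vector(m))))
  dput(obj, file = path)
  invisible(path)
}

#' @rdname saveVGAE
#' @export
loadVGAE <- function(path) {
  obj <- dget(path)
  flat <- lapply(obj$params, function(p) {
    if (is.null(p$dim)) p$values else matrix(p$values, p$dim[1], p$dim[2])
  })
  params <- unflattenAssign(initParams(obj$config, 1L), flat)
  methods::new("VGAEModel", params = params, config = obj$config,
               trained = obj$trained, trainingLog = data.frame())
}
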