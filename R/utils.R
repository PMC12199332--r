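#' @import methods
#' @importFrom stats prcomp sd var rnorm runif ecdf kmeans t.test p.adjust
#'   dnorm quantile setNames dist
#' @importFrom utils head tail
#' @importFrom data.table data.table fread fwrite setorder rbindlist
#'   as.data.table
#' @importFrom Rcpp evalCpp
#' @useDynLib scArch, .registration = TRUE
NULL

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so library code never leaks global randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a stream seed from a master seed; kept below 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Canonical integer key for an unordered bin pair (u <= v), unique for u,v < 2^26.
pairKey <- function(u, v, n) {
  pmin(u, v) * as.numeric(n) + pmax(u, v)
}

## Genomic-distance band for loop prediction, in bins (inclusive).
LOOP_BAND_MIN_BINS <- 10L   # 100 kb at 10 kb resolution
LOOP_BAND_MAX_BINS <- 100L  # 1 Mb

inLoopBand <- function(u, v, resolution = 10000L,
                       bandBp = c(1e5, 1e6)) {
  d <- abs(v - u) * as.numeric(resolution)
  d >= bandBp[1] & d <= bandBp[2]
}
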