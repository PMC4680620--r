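## Model-based Monte-Carlo mutual information for Gaussian-noise profile
## sets. This is the package's independent oracle: it makes no small-noise
## assumption and handles non-monotonic means (zigzag folds) and joint,
## multi-channel sets.

#' Numeric mutual information between position and noisy expression
#'
#' Estimates \eqn{I[\{g_i(\hat x) + \mathrm{noise}_i\}, \hat x]} for
#' \eqn{\hat x} uniform on the set's domain and independent Gaussian channel
#' noises of variance \eqn{\sigma_i(x)^2 + \eta_0^2}. Positions and
#' expression vectors are drawn by Monte Carlo; the marginal mixture density
#' \eqn{p(g) = \int p(g|x)\,dx / L} is evaluated by midpoint quadrature on an
#' \code{nGrid}-point position grid. The estimator averages pointwise
#' log-density ratios, so its standard error is reported from the sample
#' spread of those ratios.
#'
#' The quadrature grid must resolve the conditional kernels: the grid
#' spacing times the steepest mean slope has to stay below the smallest
#' noise SD. The default (\code{nGrid = NULL}) probes the channels and picks
#' a grid at least four times finer than that limit, between 512 and 8192
#' nodes.
#'
#' @param profiles a [ProfileSet-class].
#' @param eta0 extra readout noise SD added to every channel (>= 0).
#' @param nGrid number of quadrature nodes for the mixture density;
#'   \code{NULL} for automatic selection.
#' @param nMC number of Monte-Carlo draws.
#' @param seed optional integer seed.
#' @param noiseMode \code{"absolute"} (default) adds \code{eta0} directly;
#'   \code{"fractional"} adds \code{eta0 * mean(x)}.
#' @param chunkSize draws processed per block (memory control).
#' @return an [InfoResult-class] with method \code{"numeric"} and a
#'   Monte-Carlo standard error.
#' @examples
#' ps <- profileSet(linearProfile(cMax = 1, sigma = 0.02))
#' mi <- miNumeric(ps, nMC = 2000, seed = 1)
#' valueNats(mi)   # close to valueNats(infoPhi(50))
#' @export
miNumeric <- function(profiles, eta0 = 0, nGrid = NULL, nMC = 20000L,
                      seed = NULL, noiseMode = c("absolute", "fractional"),
                      chunkSize = 2000L) {
  stopifnot(is(profiles, "ProfileSet"))
  noiseMode <- match.arg(noiseMode)
  if (!is.numeric(eta0) || length(eta0) != 1L || eta0 < 0)
    stop("'eta0' must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)

  lo <- profiles@domain[1]; hi <- profiles@domain[2]
  L <- hi - lo
  if (is.null(nGrid)) nGrid <- .autoGrid(profiles, eta0, noiseMode)
  nGrid <- as.integer(nGrid); nMC <- as.integer(nMC)
  xg <- lo + (seq_len(nGrid) - 0.5) * (L / nGrid)
  nc <- length(profiles@channels)

  gridMean <- vector("list", nc)
  gridSd <- vector("list", nc)
  for (i in seq_len(nc)) {
    ch <- profiles@channels[[i]]
    m <- ch@meanFun(xg)
    s <- .totalSd(ch@sdFun(xg), m, eta0, noiseMode)
    if (any(s <= 0))
      stop("channel '", ch@gene, "' has zero total noise SD somewhere; ",
           "supply eta0 > 0 or a strictly positive noise profile")
    gridMean[[i]] <- m
    gridSd[[i]] <- s
  }

  xs <- runif(nMC, lo, hi)
  sampMean <- matrix(NA_real_, nMC, nc)
  sampSd <- matrix(NA_real_, nMC, nc)
  g <- matrix(NA_real_, nMC, nc)
  for (i in seq_len(nc)) {
    ch <- profiles@channels[[i]]
    m <- ch@meanFun(xs)
    s <- .totalSd(ch@sdFun(xs), m, eta0, noiseMode)
    if (any(s <= 0))
      stop("channel '", ch@gene, "' has zero total noise SD somewhere; ",
           "supply eta0 > 0 or a strictly positive noise profile")
    sampMean[, i] <- m
    sampSd[, i] <- s
    g[, i] <- m + s * rnorm(nMC)
  }

  logCond <- rowSums(vapply(seq_len(nc), function(i)
    dnorm(g[, i], sampMean[, i], sampSd[, i], log = TRUE),
    numeric(nMC)))

  logMarg <- numeric(nMC)
  idx <- split(seq_len(nMC), ceiling(seq_len(nMC) / as.integer(chunkSize)))
  for (jj in idx) {
    m <- length(jj)
    W <- matrix(0, nGrid, m)
    for (i in seq_len(nc))
      W <- W + dnorm(matrix(g[jj, i], nGrid, m, byrow = TRUE),
                     mean = gridMean[[i]], sd = gridSd[[i]], log = TRUE)
    Mx <- apply(W, 2L, max)
    logMarg[jj] <- Mx + log(colMeans(exp(W - rep(Mx, each = nGrid))))
  }

  l <- logCond - logMarg
  InfoResult(mean(l), "numeric", mcStderr = stats::sd(l) / sqrt(nMC),
             params = list(eta0 = eta0, nGrid = nGrid, nMC = nMC,
                           noiseMode = noiseMode,
                           channels = channelNames(profiles)))
}

## pick a quadrature grid ~4x finer than the steepest-slope / smallest-SD
## resolution limit
.autoGrid <- function(profiles, eta0, noiseMode) {
  lo <- profiles@domain[1]; hi <- profiles@domain[2]
  L <- hi - lo
  xp <- seq(lo, hi, length.out = 513L)
  ratio <- 1
  for (ch in profiles@channels) {
    m <- ch@meanFun(xp)
    s <- .totalSd(ch@sdFun(xp), m, eta0, noiseMode)
    sMin <- min(s[s > 0], Inf)
    slopeMax <- max(abs(diff(m)) / (L / 512))
    if (is.finite(sMin) && slopeMax > 0)
      ratio <- max(ratio, L * slopeMax / sMin)
  }
  as.integer(min(8192, max(512, ceiling(4 * ratio))))
}

.totalSd <- function(sdVals, meanVals, eta0, noiseMode) {
  extra <- if (noiseMode == "absolute") eta0 else eta0 * meanVals
  sqrt(sdVals^2 + extra^2)
}
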