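## The empirical analysis pipeline: nucleus table -> neighbor-noise
## estimates -> idealized spline profiles -> ROI information -> accessible
## information curves -> noiseless-pair bound -> crossing point.

#' Estimate expression noise from dorsal/ventral neighbor differences
#'
#' Nuclei in the same AP row but adjacent DV columns share their position and
#' hence their mean expression, so the RMS of their expression differences,
#' binned along the AP axis, measures pure noise: under independent
#' per-nucleus fluctuations the per-nucleus SD is \code{RMS / sqrt(2)}. When
#' a list of embryo replicates is given, per-bin estimates are averaged
#' across embryos and their across-embryo spread reported.
#'
#' @param table a [NucleusTable-class], or a list of them (replicates).
#' @param gene gene name.
#' @param bins number of AP bins over \code{domain}.
#' @param domain binning interval, default \code{c(0, 1)}.
#' @return a [NoiseProfileEstimate-class]; bins with fewer than two neighbor
#'   pairs are \code{NA}.
#' @export
estimateNeighborNoise <- function(table, gene, bins = 50L,
                                  domain = c(0, 1)) {
  if (is.list(table) && !is(table, "NucleusTable")) {
    parts <- lapply(table, estimateNeighborNoise, gene = gene, bins = bins,
                    domain = domain)
    sdMat <- vapply(parts, function(p) p@sd, numeric(bins))
    rmsMat <- vapply(parts, function(p) p@rms, numeric(bins))
    nMat <- vapply(parts, function(p) p@nPairs, integer(bins))
    return(new("NoiseProfileEstimate", gene = gene,
               breaks = parts[[1]]@breaks, mid = parts[[1]]@mid,
               rms = rowMeans(rmsMat, na.rm = TRUE),
               sd = rowMeans(sdMat, na.rm = TRUE),
               nPairs = as.integer(rowSums(nMat)),
               replicateSD = apply(sdMat, 1L, stats::sd, na.rm = TRUE),
               nReplicates = length(parts)))
  }
  stopifnot(is(table, "NucleusTable"))
  if (!gene %in% rownames(table))
    stop(sprintf("gene '%s' is not in the table", gene))
  dv <- dvIndex(table)
  if (length(unique(dv)) < 2L)
    stop("neighbor-noise estimation needs at least 2 DV columns")
  x <- apPosition(table)
  e <- SummarizedExperiment::assay(table, "expression")[gene, ]
  key <- paste(x, dv)
  partner <- match(paste(x, dv + 1L), key)
  ok <- !is.na(partner)
  d <- e[ok] - e[partner[ok]]
  px <- x[ok]

  bins <- as.integer(bins)
  breaks <- seq(domain[1], domain[2], length.out = bins + 1L)
  bin <- cut(px, breaks, include.lowest = TRUE, labels = FALSE)
  rms <- sdv <- rep(NA_real_, bins)
  nP <- integer(bins)
  for (b in seq_len(bins)) {
    db <- d[which(bin == b)]
    nP[b] <- length(db)
    if (nP[b] >= 2L) {
      rms[b] <- sqrt(mean(db^2))
      sdv[b] <- rms[b] / sqrt(2)
    }
  }
  new("NoiseProfileEstimate", gene = gene, breaks = breaks,
      mid = (breaks[-1] + breaks[-(bins + 1L)]) / 2, rms = rms, sd = sdv,
      nPairs = nP, replicateSD = rep(NA_real_, bins), nReplicates = 1L)
}

#' Fit an idealized Gaussian-noise profile to nucleus data
#'
#' Produces the channel the information estimators consume: a smoothing
#' spline through the pooled per-nucleus expression values gives the mean
#' shape, and a second smoothing spline through the binned neighbor-noise SD
#' estimates gives the noise profile. Both are then normalized so the fitted
#' mean's maximum over \code{domain} equals 1, putting all genes on a common
#' expression scale. Smoothing is chosen by generalized cross-validation
#' unless \code{spar} is given.
#'
#' @param table a [NucleusTable-class] or list of replicates.
#' @param gene gene name.
#' @param domain fit/normalization domain, default the full axis.
#' @param spar optional smoothing parameter for the mean spline
#'   (see [stats::smooth.spline()]).
#' @param bins AP bins for the noise estimate.
#' @param normalize rescale so the fitted mean peaks at 1.
#' @return an [ExpressionProfile-class]; its \code{scale} slot records the
#'   normalization factor.
#' @export
fitIdealizedProfile <- function(table, gene, domain = c(0, 1), spar = NULL,
                                bins = 50L, normalize = TRUE) {
  tables <- if (is.list(table) && !is(table, "NucleusTable")) table
            else list(table)
  x <- unlist(lapply(tables, apPosition))
  e <- unlist(lapply(tables, function(t)
    SummarizedExperiment::assay(t, "expression")[gene, ]))
  keep <- x >= domain[1] & x <= domain[2]
  x <- x[keep]; e <- e[keep]
  if (length(unique(x)) < 10L)
    stop("need at least 10 distinct AP positions in the domain")
  meanFit <- if (is.null(spar)) smooth.spline(x, e)
             else smooth.spline(x, e, spar = spar)

  noise <- estimateNeighborNoise(tables, gene, bins = bins, domain = domain)
  okBin <- is.finite(noise@sd)
  if (sum(okBin) < 4L)
    stop("too few usable noise bins to fit a noise profile")
  sdFit <- smooth.spline(noise@mid[okBin], noise@sd[okBin],
                         df = min(6, sum(okBin) - 1L))

  scale <- if (normalize) {
    xs <- seq(domain[1], domain[2], length.out = 512L)
    max(predict(meanFit, xs)$y)
  } else 1
  force(meanFit); force(sdFit); force(scale)
  ExpressionProfile(gene,
    meanFun = function(x) predict(meanFit, x)$y / scale,
    sdFun = function(x) pmax(predict(sdFit, x)$y, 0) / scale,
    domain = as.numeric(domain), scale = scale)
}

#' Accessible information as a function of readout noise
#'
#' Evaluates the small-noise information of the profile set at each readout
#' noise magnitude in \code{eta0Grid}, treating the readout noise as a
#' variable parameter. The decay of the curve characterizes how tolerant the
#' encoded information is to added readout noise.
#'
#' @param profiles a [ProfileSet-class].
#' @param eta0Grid non-negative readout noise values.
#' @param noiseMode \code{"absolute"} or \code{"fractional"} readout noise.
#' @param nGrid quadrature nodes for [infoSmallNoise()].
#' @return a \code{data.frame} with columns \code{eta0}, \code{nats},
#'   \code{bits}, \code{infinite} (always \code{FALSE} here; kept for
#'   symmetry with [noiselessPairBound()]).
#' @export
accInfoCurve <- function(profiles, eta0Grid,
                         noiseMode = c("absolute", "fractional"),
                         nGrid = 512L) {
  noiseMode <- match.arg(noiseMode)
  nats <- vapply(eta0Grid, function(e)
    valueNats(infoSmallNoise(profiles, eta0 = e, nGrid = nGrid,
                             noiseMode = noiseMode)), numeric(1))
  data.frame(eta0 = eta0Grid, nats = nats, bits = nats / log(2),
             infinite = FALSE)
}

#' Best-case bound: the input pair rendered noiseless
#'
#' The same curve as [accInfoCurve()], but with every channel's own
#' expression noise forced to zero so only the readout noise remains — the
#' theoretical best case for any strategy restricted to those channels. At
#' \code{eta0 = 0} the value diverges; such grid entries are returned as
#' \code{Inf} with \code{infinite = TRUE} and are never interpolated through.
#'
#' @param profiles a [ProfileSet-class].
#' @param eta0Grid non-negative readout noise values.
#' @param genes channels to keep (default: all).
#' @param nGrid quadrature nodes.
#' @return a \code{data.frame} with columns \code{eta0}, \code{nats},
#'   \code{bits}, \code{infinite}.
#' @export
noiselessPairBound <- function(profiles, eta0Grid, genes = NULL,
                               nGrid = 512L) {
  stopifnot(is(profiles, "ProfileSet"))
  channels <- profiles@channels
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(channels))
    if (length(missing))
      stop("channel(s) not in the set: ", paste(missing, collapse = ", "))
    channels <- channels[genes]
  }
  channels <- lapply(channels, function(ch) {
    ch@sdFun <- function(x) rep(0, length(x))
    ch
  })
  noiseless <- profileSet(channels, domain = profiles@domain)
  nats <- vapply(eta0Grid, function(e) {
    if (e == 0) return(Inf)
    valueNats(infoSmallNoise(noiseless, eta0 = e, nGrid = nGrid))
  }, numeric(1))
  data.frame(eta0 = eta0Grid, nats = nats, bits = nats / log(2),
             infinite = !is.finite(nats))
}

#' Locate where the triplet curve crosses above the bound
#'
#' Finds the smallest readout noise at which the triplet's accessible
#' information meets or exceeds the noiseless-pair bound. The two curves must
#' share their \code{eta0} grid. The grid crossing is bracketed by the sign
#' change and, when the closed-form curve functions are supplied, refined by
#' bisection; otherwise it is linearly interpolated between the bracketing
#' grid points.
#'
#' @param bound,triplet \code{data.frame}s from [noiselessPairBound()] and
#'   [accInfoCurve()] on a common grid.
#' @param boundFun,tripletFun optional functions \code{eta0 -> bits} used for
#'   bisection refinement.
#' @param tol bisection tolerance on eta0.
#' @return a [CrossingResult-class].
#' @export
findCrossing <- function(bound, triplet, boundFun = NULL, tripletFun = NULL,
                         tol = 1e-6) {
  if (nrow(bound) != nrow(triplet) ||
      any(abs(bound$eta0 - triplet$eta0) > 1e-12))
    stop("'bound' and 'triplet' must share the same eta0 grid")
  eta0 <- bound$eta0
  d <- triplet$bits - bound$bits          # -Inf where the bound diverges
  above <- which(d >= 0)
  if (!length(above))
    return(new("CrossingResult", eta0 = eta0, boundBits = bound$bits,
               tripletBits = triplet$bits, crossing = NA_real_,
               bracket = c(NA_real_, NA_real_)))
  i <- above[1]
  if (i == 1L || d[i] == 0) {
    crossing <- eta0[i]
    bracket <- c(NA_real_, NA_real_)
  } else {
    lo <- eta0[i - 1L]; hi <- eta0[i]
    bracket <- c(lo, hi)
    if (!is.null(boundFun) && !is.null(tripletFun) && is.finite(d[i - 1L])) {
      f <- function(e) tripletFun(e) - boundFun(e)
      while (hi - lo > tol) {
        midp <- (lo + hi) / 2
        if (f(midp) >= 0) hi <- midp else lo <- midp
      }
      crossing <- (lo + hi) / 2
    } else {
      ## linear interpolation across the sign change (finite d only)
      crossing <- if (is.finite(d[i - 1L]))
        lo + (hi - lo) * (-d[i - 1L]) / (d[i] - d[i - 1L])
      else hi
    }
  }
  new("CrossingResult", eta0 = eta0, boundBits = bound$bits,
      tripletBits = triplet$bits, crossing = crossing, bracket = bracket)
}

#' Pipeline configuration
#'
#' Collects the tunable settings of [runPipeline()] with the defaults the
#' package uses throughout: the 0.37-0.47 region of interest where the two
#' gap-like boundaries oppose each other, 50 AP bins for noise estimation, a
#' logarithmic readout-noise grid (expression units, i.e. fractions of the
#' normalized maximum) with an explicit zero entry for the divergent bound,
#' absolute readout noise, and 8 synthetic embryo replicates.
#'
#' @param roi region of interest.
#' @param bins AP bins for the neighbor-noise estimate.
#' @param eta0Grid readout-noise grid for the curves.
#' @param noiseMode \code{"absolute"} or \code{"fractional"} readout noise.
#' @param nEmbryos replicates generated when the input is an
#'   [EmbryoSpec-class].
#' @param pairGenes channels of the input pair (default: first two genes).
#' @param tripletGenes channels of the full set (default: all genes).
#' @param spar optional smoothing parameter passed to
#'   [fitIdealizedProfile()].
#' @param domain full-axis fitting/normalization domain.
#' @return a named list.
#' @export
pipelineConfig <- function(roi = c(0.37, 0.47), bins = 50L,
                           eta0Grid = c(0, 10^seq(-2.5, 0.5,
                                                  length.out = 30L)),
                           noiseMode = c("absolute", "fractional"),
                           nEmbryos = 8L, pairGenes = NULL,
                           tripletGenes = NULL, spar = NULL,
                           domain = c(0, 1)) {
  list(roi = as.numeric(roi), bins = as.integer(bins),
       eta0Grid = as.numeric(eta0Grid), noiseMode = match.arg(noiseMode),
       nEmbryos = as.integer(nEmbryos), pairGenes = pairGenes,
       tripletGenes = tripletGenes, spar = spar,
       domain = as.numeric(domain))
}

#' Run the full empirical analysis
#'
#' Executes the whole chain on synthetic or supplied data: generate (or
#' accept) embryo replicates, estimate per-gene expression noise from
#' dorsal/ventral neighbor differences, fit idealized normalized profiles,
#' restrict to the region of interest, compute each gene's positional
#' information there, trace the accessible-information curve of the full
#' triplet and the noiseless bound of the input pair over the readout-noise
#' grid, and locate their crossing.
#'
#' @param x an [EmbryoSpec-class] (replicates are generated), a
#'   [NucleusTable-class], or a list of \code{NucleusTable}s.
#' @param config settings from [pipelineConfig()].
#' @param seed optional integer seed; all randomness in the run flows from
#'   it.
#' @return a report: a named list with elements \code{genes}, \code{roi},
#'   \code{perGeneBits}, \code{noise} (per-gene binned SD estimates and
#'   replicate spread), \code{tripletCurve}, \code{pairBound},
#'   \code{crossingEta0}, \code{crossingBracket}, \code{config} and
#'   \code{seed}. Write it with [writeReport()].
#' @examples
#' \donttest{
#' rep <- runPipeline(EmbryoSpec(nAP = 60L, nDV = 6L),
#'                    config = pipelineConfig(nEmbryos = 2L, bins = 25L),
#'                    seed = 1)
#' rep$perGeneBits
#' }
#' @export
runPipeline <- function(x, config = pipelineConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tables <- if (is(x, "EmbryoSpec")) {
    lapply(seq_len(config$nEmbryos), function(i) generateEmbryo(x))
  } else if (is(x, "NucleusTable")) list(x)
  else if (is.list(x) && all(vapply(x, is, logical(1), "NucleusTable"))) x
  else stop("'x' must be an EmbryoSpec, a NucleusTable, or a list of them")

  genes <- rownames(tables[[1]])
  pairGenes <- if (is.null(config$pairGenes)) genes[1:2] else config$pairGenes
  tripletGenes <- if (is.null(config$tripletGenes)) genes
                  else config$tripletGenes

  noise <- lapply(setNames(genes, genes), function(g)
    estimateNeighborNoise(tables, g, bins = config$bins,
                          domain = config$domain))
  profiles <- lapply(setNames(genes, genes), function(g)
    fitIdealizedProfile(tables, g, domain = config$domain,
                        spar = config$spar, bins = config$bins))
  fullSet <- profileSet(profiles, domain = config$domain)
  roiSet <- roiRestrict(fullSet, config$roi)

  perGeneBits <- vapply(setNames(genes, genes), function(g)
    valueBits(infoSmallNoise(profileSet(list(roiSet@channels[[g]]),
                                        domain = config$roi),
                             noiseMode = config$noiseMode)), numeric(1))

  tripletSet <- profileSet(roiSet@channels[tripletGenes],
                           domain = config$roi)
  tripletCurve <- accInfoCurve(tripletSet, config$eta0Grid,
                               noiseMode = config$noiseMode)
  pairSet <- profileSet(roiSet@channels[pairGenes], domain = config$roi)
  bound <- noiselessPairBound(pairSet, config$eta0Grid)

  boundFun <- function(e) noiselessPairBound(pairSet, e)$bits
  tripletFun <- function(e)
    accInfoCurve(tripletSet, e, noiseMode = config$noiseMode)$bits
  crossing <- findCrossing(bound, tripletCurve, boundFun = boundFun,
                           tripletFun = tripletFun)

  list(genes = genes, roi = config$roi, pairGenes = pairGenes,
       tripletGenes = tripletGenes, perGeneBits = perGeneBits,
       noise = lapply(noise, function(np)
         list(mid = np@mid, sd = np@sd, rms = np@rms,
              nPairs = np@nPairs, replicateSD = np@replicateSD)),
       tripletCurve = tripletCurve, pairBound = bound,
       crossingEta0 = crossingPoint(crossing),
       crossingBracket = crossing@bracket,
       nEmbryos = length(tables),
       config = config[c("roi", "bins", "eta0Grid", "noiseMode", "domain")],
       seed = if (is.null(seed)) NA_integer_ else seed)
}
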